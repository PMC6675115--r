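#' Simulate gene sets, genetic map and QTL table with known truth
#'
#' Builds the annotation resources the prioritization stages consume, with
#' ground truth tied to the planted candidate genes: a gene set labelled
#' with a trait-relevance keyword whose members are exactly the planted
#' candidates (so it is strongly over-represented in any query containing
#' them), whitelist-named pathway sets containing the candidates plus
#' SNV-free decoy genes, and neutral background sets; a strictly increasing
#' per-chromosome (bp, cM) anchor map; and a QTL table with, for every
#' planted candidate gene, one milk-trait QTL whose peak lies strictly
#' within 1 cM of the gene's interpolated position, plus per-chromosome
#' decoy QTLs at least 3 cM from every gene.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble from [simulate_reference()].
#' @param truth_genes Planted candidate gene tibble from
#'   [simulate_cohort()].
#' @param truth_sites Planted site tibble (used to pick SNV-free decoys).
#' @return A list: `gene_sets`, `genetic_map`, `qtl_table` (with parsed
#'   `peaks` list-column).
#' @export
simulate_annotation_resources <- function(config, genes, truth_genes,
                                          truth_sites) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(
    config$seed + 2L,
    simulate_resources_impl(config, genes, truth_genes, truth_sites)
  )
}

simulate_resources_impl <- function(config, genes, truth_genes, truth_sites) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chromosome_length_bp

  map <- bind_rows(lapply(chroms, function(ch) {
    bp <- unique(as.integer(round(seq(1, L, length.out = 6))))
    inc <- runif(length(bp) - 1, 3, 6)
    tibble(chromosome = ch, bp = bp, cM = c(0, round(cumsum(inc), 4)))
  }))

  cand <- truth_genes$gene_id
  hit_genes <- unique(truth_sites$gene_id[!is.na(truth_sites$gene_id)])
  quiet_genes <- setdiff(genes$gene_id, hit_genes)

  sets <- list(
    tibble(
      set_id = "SIM0001", label = "lipid metabolic process",
      genes = list(cand)
    ),
    tibble(
      set_id = "SIM0002", label = "PPAR signaling pathway",
      genes = list(sort(unique(c(
        cand, head(sort(quiet_genes), 2)
      ))))
    ),
    tibble(
      set_id = "SIM0003", label = "insulin signaling pathway",
      genes = list(sort(unique(c(
        head(cand, 1), head(sort(quiet_genes), 4)
      ))))
    )
  )
  neutral_labels <- c(
    "cell cycle", "DNA repair", "ion transport", "ribosome biogenesis",
    "chromatin organization"
  )
  for (i in seq_along(neutral_labels)) {
    size <- sample(6:12, 1)
    sets[[length(sets) + 1L]] <- tibble(
      set_id = sprintf("SIM%04d", i + 3L),
      label = neutral_labels[i],
      genes = list(sort(sample(genes$gene_id, min(size, nrow(genes)))))
    )
  }
  gene_sets <- bind_rows(sets) %>% mutate(collection = "custom")

  gene_cm <- genes %>%
    group_by(.data$chromosome) %>%
    mutate(cm = interpolate_cm(map, .data$chromosome[1], .data$start)) %>%
    ungroup()

  traits <- c("PP", "PY", "FP", "FY")
  qtl_rows <- list()
  for (j in seq_along(cand)) {
    g <- gene_cm %>% filter(.data$gene_id == cand[j])
    offset <- runif(1, 0.05, 0.85)
    if (g$cm - offset < 0 || sample(c(TRUE, FALSE), 1)) {
      peak <- g$cm + offset
    } else {
      peak <- g$cm - offset
    }
    peak <- round(peak, 3)
    peaks <- if (j == 1) c(peak, peak + 5) else peak
    qtl_rows[[j]] <- tibble(
      chromosome = g$chromosome, trait = traits[(j - 1L) %% 4L + 1L],
      ci_start_cM = max(0, round(peak - 2, 3)),
      ci_end_cM = round(max(peaks) + 2, 3),
      peaks = list(peaks), source = "SimStudy2026"
    )
  }
  for (i in seq_along(chroms)) {
    on_chr <- gene_cm %>% filter(.data$chromosome == chroms[i])
    base <- if (nrow(on_chr) > 0) max(on_chr$cm) else 0
    peak <- round(base + 3.5 + runif(1, 0, 0.5), 3)
    qtl_rows[[length(qtl_rows) + 1L]] <- tibble(
      chromosome = chroms[i], trait = traits[(i - 1L) %% 4L + 1L],
      ci_start_cM = round(peak - 2, 3), ci_end_cM = round(peak + 2, 3),
      peaks = list(peak), source = "SimDecoy"
    )
  }
  qtl_table <- bind_rows(qtl_rows)

  list(gene_sets = gene_sets, genetic_map = map, qtl_table = qtl_table)
}

#' Simulate and write a complete study to a directory
#'
#' Runs [simulate_reference()], [simulate_cohort()] and
#' [simulate_annotation_resources()] and writes every input the pipeline
#' consumes: `reference.fa`, `genes.gff3`, one VCF per sample under `vcf/`
#' plus a merged `cohort.vcf`, `design.csv`, `gene_sets.gmt`,
#' `genetic_map.csv`, `qtl_table.csv`, and the ground truth
#' (`truth_sites.csv`, `truth_genes.csv`). All outputs are byte-identical
#' across runs with the same configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the simulated objects and a `paths`
#'   element suitable for [run_pipeline()] via [pipeline_inputs()].
#' @export
simulate_study <- function(config, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config)
  cohort <- simulate_cohort(config, ref$reference, ref$genes, ref$features)
  res <- simulate_annotation_resources(
    config, ref$genes, cohort$truth_genes, cohort$truth_sites
  )

  contig_lengths <- setNames(
    Biostrings::width(ref$reference), names(ref$reference)
  )
  write_reference_fasta(ref$reference, file.path(dir, "reference.fa"))
  write_gff3(
    ref$genes, ref$features, file.path(dir, "genes.gff3"), contig_lengths
  )
  for (s in cohort$samples) {
    write_sample_vcf(
      cohort$calls, s, file.path(dir, "vcf", paste0(s, ".vcf")),
      contig_lengths
    )
  }
  write_cohort_vcf(
    cohort$calls, cohort$samples, file.path(dir, "cohort.vcf"),
    contig_lengths
  )
  write_family_design(cohort$design, file.path(dir, "design.csv"))
  write_gmt(res$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_genetic_map(res$genetic_map, file.path(dir, "genetic_map.csv"))
  write_qtl_table(res$qtl_table, file.path(dir, "qtl_table.csv"))
  readr::write_csv(
    cohort$truth_sites, file.path(dir, "truth_sites.csv"),
    progress = FALSE
  )
  readr::write_csv(
    cohort$truth_genes, file.path(dir, "truth_genes.csv"),
    progress = FALSE
  )

  invisible(list(
    reference = ref$reference, genes = ref$genes, features = ref$features,
    calls = cohort$calls, design = cohort$design, samples = cohort$samples,
    truth_sites = cohort$truth_sites, truth_genes = cohort$truth_genes,
    gene_sets = res$gene_sets, genetic_map = res$genetic_map,
    qtl_table = res$qtl_table,
    paths = pipeline_inputs(dir)
  ))
}

#' Locate the standard input files of a study directory
#'
#' @param dir A directory written by [simulate_study()] (or following the
#'   same layout).
#' @return A named list of paths consumable by [run_pipeline()].
#' @export
pipeline_inputs <- function(dir) {
  list(
    vcfs = sort(list.files(
      file.path(dir, "vcf"),
      pattern = "\\.vcf(\\.gz)?$", full.names = TRUE
    )),
    design = file.path(dir, "design.csv"),
    gff = file.path(dir, "genes.gff3"),
    fasta = file.path(dir, "reference.fa"),
    gmt = file.path(dir, "gene_sets.gmt"),
    genetic_map = file.path(dir, "genetic_map.csv"),
    qtl_table = file.path(dir, "qtl_table.csv")
  )
}
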