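CATEGORY_PRIORITY <- c(
  exonic = 1, UTR5 = 2, UTR3 = 3, intronic = 4,
  ncRNA_exonic = 5, ncRNA_intronic = 6
)

ref_bases <- function(reference, chromosome, positions) {
  if (length(positions) == 0) {
    return(character(0))
  }
  as.character(Biostrings::extractAt(
    reference[[chromosome]], IRanges::IRanges(positions, positions)
  ))
}

#' Assign a functional category to each SNV
#'
#' Classifies every site against the gene models, mirroring the
#' region-annotation conventions of ANNOVAR-style tools. Inside a coding
#' gene a site is `exonic` (in CDS; coding effect computed via
#' [coding_effect()]), `UTR5`/`UTR3` (in a UTR) or `intronic`; inside an
#' ncRNA gene, `ncRNA_exonic`/`ncRNA_intronic`. Outside all genes, a site
#' within `near_gene_bp` (default 1 kb, boundary-inclusive) of a gene is
#' `upstream` or `downstream` (strand-aware: upstream is the 5' side), or
#' `upstream;downstream` when simultaneously within the window upstream of
#' one gene and downstream of a different gene; anything farther from every
#' gene is `intergenic`.
#'
#' When a site matches several features the highest-priority one wins
#' (exonic > UTR5 > UTR3 > intronic > ncRNA_exonic > ncRNA_intronic >
#' up/downstream > intergenic); among equal-priority genes the nearest gene
#' wins, ties broken by the lexicographically smaller gene id. Sites whose
#' stated reference allele disagrees with the reference sequence are
#' flagged (`ref_mismatch`), never dropped.
#'
#' @param snvs Tibble with columns `chromosome`, `position`, `ref`, `alt`.
#' @param genes,features Gene-model tibbles (see [read_gene_models()]).
#' @param reference Named [Biostrings::DNAStringSet] covering every site.
#' @param config A [pipeline_config()].
#' @return An annotation tibble: the site columns plus `category`,
#'   `exonic_effect` (`not_applicable` unless exonic), `gene_id` (NA for
#'   intergenic), `distance_bp` (0 inside a gene, else nearest-boundary
#'   distance) and `ref_mismatch`.
#' @export
assign_category <- function(snvs, genes, features, reference,
                            config = pipeline_config()) {
  unknown <- setdiff(unique(snvs$chromosome), names(reference))
  if (length(unknown) > 0) {
    stop_bad_arg(paste0(
      "sites on chromosomes absent from the reference: ",
      paste(unknown, collapse = ", ")
    ))
  }
  n <- nrow(snvs)
  site_gr <- GenomicRanges::GRanges(
    snvs$chromosome, IRanges::IRanges(snvs$position, snvs$position)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chromosome, IRanges::IRanges(genes$start, genes$end)
  )

  genome_base <- vapply(seq_len(n), function(i) {
    ref_bases(reference, snvs$chromosome[i], snvs$position[i])
  }, character(1))
  ref_mismatch <- genome_base != snvs$ref

  # --- genic classification -------------------------------------------------
  ov <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  pairs <- tibble(
    site = S4Vectors::queryHits(ov),
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    biotype = genes$biotype[S4Vectors::subjectHits(ov)]
  )
  feat <- features %>%
    semi_join(genes, by = "gene_id") %>%
    inner_join(genes %>% select("gene_id", "chromosome"), by = "gene_id")
  feat_gr <- GenomicRanges::GRanges(
    feat$chromosome, IRanges::IRanges(feat$start, feat$end)
  )
  ovf <- GenomicRanges::findOverlaps(site_gr, feat_gr)
  fhits <- tibble(
    site = S4Vectors::queryHits(ovf),
    gene_id = feat$gene_id[S4Vectors::subjectHits(ovf)],
    ftype = feat$type[S4Vectors::subjectHits(ovf)]
  ) %>%
    distinct() %>%
    mutate(hit = TRUE) %>%
    tidyr::pivot_wider(
      names_from = "ftype", values_from = "hit", values_fill = FALSE
    )
  for (col in c("CDS", "five_prime_UTR", "three_prime_UTR", "exon")) {
    if (!col %in% names(fhits)) fhits[[col]] <- FALSE
  }
  genic <- pairs %>%
    left_join(fhits, by = c("site", "gene_id")) %>%
    mutate(across(
      c("CDS", "five_prime_UTR", "three_prime_UTR", "exon"),
      ~ tidyr::replace_na(.x, FALSE)
    )) %>%
    mutate(category = case_when(
      .data$biotype == "coding" & .data$CDS ~ "exonic",
      .data$biotype == "coding" & .data$five_prime_UTR ~ "UTR5",
      .data$biotype == "coding" & .data$three_prime_UTR ~ "UTR3",
      .data$biotype == "coding" ~ "intronic",
      .data$exon ~ "ncRNA_exonic",
      TRUE ~ "ncRNA_intronic"
    )) %>%
    mutate(priority = CATEGORY_PRIORITY[.data$category]) %>%
    group_by(.data$site) %>%
    arrange(.data$priority, .data$gene_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()

  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  distance_bp <- rep(NA_real_, n)
  category[genic$site] <- genic$category
  gene_id[genic$site] <- genic$gene_id
  distance_bp[genic$site] <- 0

  # --- near-gene (up/downstream) classification -----------------------------
  outside <- which(is.na(category))
  if (length(outside) > 0 && nrow(genes) > 0) {
    w <- config$near_gene_bp
    up_first <- genes$strand == "+" # upstream flank adjoins the span start
    flanks <- bind_rows(
      tibble(
        gene_id = genes$gene_id, chromosome = genes$chromosome,
        side = ifelse(up_first, "upstream", "downstream"),
        start = pmax(1L, genes$start - as.integer(w)),
        end = genes$start - 1L,
        gstart = genes$start, gend = genes$end
      ),
      tibble(
        gene_id = genes$gene_id, chromosome = genes$chromosome,
        side = ifelse(up_first, "downstream", "upstream"),
        start = genes$end + 1L,
        end = genes$end + as.integer(w),
        gstart = genes$start, gend = genes$end
      )
    ) %>% filter(.data$end >= .data$start)
    flank_gr <- GenomicRanges::GRanges(
      flanks$chromosome, IRanges::IRanges(flanks$start, flanks$end)
    )
    ovn <- GenomicRanges::findOverlaps(site_gr[outside], flank_gr)
    near <- tibble(
      site = outside[S4Vectors::queryHits(ovn)],
      gene_id = flanks$gene_id[S4Vectors::subjectHits(ovn)],
      side = flanks$side[S4Vectors::subjectHits(ovn)],
      gstart = flanks$gstart[S4Vectors::subjectHits(ovn)],
      gend = flanks$gend[S4Vectors::subjectHits(ovn)]
    ) %>%
      mutate(
        pos = snvs$position[.data$site],
        dist = pmin(
          abs(.data$pos - .data$gstart), abs(.data$pos - .data$gend)
        )
      )
    if (nrow(near) > 0) {
      picked <- near %>%
        group_by(.data$site) %>%
        summarise(
          both = dplyr::n_distinct(.data$side) == 2 &&
            dplyr::n_distinct(.data$gene_id) >= 2,
          side = .data$side[order(.data$dist, .data$gene_id)][1],
          gene_id = .data$gene_id[order(.data$dist, .data$gene_id)][1],
          dist = min(.data$dist),
          .groups = "drop"
        ) %>%
        mutate(category = ifelse(
          .data$both, "upstream;downstream", .data$side
        ))
      category[picked$site] <- picked$category
      gene_id[picked$site] <- picked$gene_id
      distance_bp[picked$site] <- picked$dist
    }
  }

  # --- intergenic -----------------------------------------------------------
  inter <- which(is.na(category))
  if (length(inter) > 0) {
    category[inter] <- "intergenic"
    if (nrow(genes) > 0) {
      dtn <- GenomicRanges::distanceToNearest(site_gr[inter], gene_gr)
      # GRanges distance counts the gap; the nearest-boundary distance is
      # one more for non-overlapping ranges
      distance_bp[inter[S4Vectors::queryHits(dtn)]] <-
        S4Vectors::mcols(dtn)$distance + 1
    }
  }

  # --- coding effects -------------------------------------------------------
  exonic_effect <- rep("not_applicable", n)
  ex_sites <- which(category == "exonic")
  for (i in ex_sites) {
    g <- gene_id[i]
    gstrand <- genes$strand[genes$gene_id == g]
    txs <- features %>%
      filter(.data$gene_id == g, .data$type == "CDS") %>%
      group_by(.data$transcript_id) %>%
      filter(any(
        snvs$position[i] >= .data$start & snvs$position[i] <= .data$end
      )) %>%
      ungroup()
    tx <- sort(unique(txs$transcript_id))[1]
    cds <- txs %>% filter(.data$transcript_id == tx)
    exonic_effect[i] <- coding_effect(
      snvs$position[i], snvs$ref[i], snvs$alt[i],
      cds, gstrand, reference, snvs$chromosome[i]
    )
  }

  snvs %>%
    select("chromosome", "position", "ref", "alt") %>%
    mutate(
      category = category,
      exonic_effect = exonic_effect,
      gene_id = gene_id,
      distance_bp = distance_bp,
      ref_mismatch = ref_mismatch
    )
}

#' Coding effect of a single-base substitution
#'
#' Builds the reference codon from the spliced CDS in strand orientation,
#' substitutes the alternate base (reverse-complemented on the minus
#' strand), and translates both codons with the standard genetic code:
#' identical amino acids give `synonymous`, a non-stop change
#' `nonsynonymous`, a created stop `stopgain`, a lost stop `stoploss`. A CDS
#' whose length is not divisible by 3, or whose reference sequence
#' disagrees with the record's reference allele, yields `unknown`.
#'
#' @param position 1-based genomic position (must lie inside `cds`).
#' @param ref,alt Reference and alternate bases on the plus strand.
#' @param cds Tibble of CDS intervals (`start`, `end`) for one transcript.
#' @param strand `"+"` or `"-"`.
#' @param reference Named [Biostrings::DNAStringSet].
#' @param chromosome Chromosome id of the site.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stopgain"`,
#'   `"stoploss"`, `"unknown"`.
#' @export
coding_effect <- function(position, ref, alt, cds, strand, reference,
                          chromosome) {
  cds <- cds %>% arrange(.data$start)
  lens <- cds$end - cds$start + 1L
  total <- sum(lens)
  ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  gpos <- unlist(lapply(ord, function(r) {
    if (strand == "+") seq(cds$start[r], cds$end[r]) else seq(cds$end[r], cds$start[r])
  }))
  idx <- match(position, gpos)
  if (is.na(idx)) {
    stop_bad_arg("site does not fall inside the transcript's CDS")
  }
  if (total %% 3L != 0L) {
    return("unknown")
  }
  if (ref_bases(reference, chromosome, position) != ref) {
    return("unknown")
  }
  codon_i <- (idx - 1L) %/% 3L
  slots <- gpos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  bases <- vapply(
    slots, function(p) ref_bases(reference, chromosome, p), character(1)
  )
  if (strand == "-") bases <- unname(COMPLEMENT[bases])
  ref_codon <- paste(bases, collapse = "")
  alt_base <- if (strand == "-") unname(COMPLEMENT[alt]) else alt
  bases[(idx - 1L) %% 3L + 1L] <- alt_base
  alt_codon <- paste(bases, collapse = "")
  aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_alt == "*") {
    "stopgain"
  } else if (aa_ref == "*") {
    "stoploss"
  } else {
    "nonsynonymous"
  }
}

#' Attach SNVs to genes within the attachment window
#'
#' An SNV is attached to every gene that contains it or whose nearest
#' boundary lies within `gene_window_bp` (default 5 kb, inclusive). SNVs
#' attached to no gene are excluded from gene-level analyses downstream.
#'
#' @param diffs Differential SNV tibble (needs `chromosome`, `position`;
#'   other columns are carried through).
#' @param genes Gene tibble.
#' @param config A [pipeline_config()].
#' @param coding_only Restrict the attachment universe to protein-coding
#'   genes (default), matching a protein-coding gene-set analysis.
#' @return A tibble with one row per (SNV, gene) assignment: the input
#'   columns plus `gene_id` and `distance_bp`. The number of distinct SNVs
#'   retained is attached as attribute `"n_retained"`.
#' @export
attach_to_genes <- function(diffs, genes, config = pipeline_config(),
                            coding_only = TRUE) {
  universe <- if (coding_only) {
    genes %>% filter(.data$biotype == "coding")
  } else {
    genes
  }
  out <- diffs %>%
    inner_join(
      universe %>%
        select("gene_id", "chromosome", gene_start = "start", gene_end = "end"),
      by = "chromosome", relationship = "many-to-many"
    ) %>%
    mutate(distance_bp = ifelse(
      .data$position >= .data$gene_start & .data$position <= .data$gene_end,
      0,
      pmin(
        abs(.data$position - .data$gene_start),
        abs(.data$position - .data$gene_end)
      )
    )) %>%
    filter(.data$distance_bp <= config$gene_window_bp) %>%
    select(-"gene_start", -"gene_end") %>%
    arrange_sites()
  attr(out, "n_retained") <- out %>%
    distinct(.data$chromosome, .data$position) %>%
    nrow()
  out
}

#' Summarize annotations into a category table
#'
#' Tallies annotation records per functional category and computes
#' percentages of the annotated total (rounded half-up to two decimals,
#' following the usual printed-table convention). Exonic records are also
#' broken down by coding effect; the breakdown rows carry no percentage,
#' and their counts sum to the exonic total.
#'
#' @param annotations Annotation tibble from [assign_category()].
#' @return A `category_summary` tibble (`category`, `effect`, `count`,
#'   `percentage`) with the annotated total as attribute
#'   `"total_annotated"`.
#' @export
summarize_categories <- function(annotations) {
  if (nrow(annotations) == 0) {
    stop_bad_arg("cannot summarize an empty annotation set")
  }
  cat_counts <- annotations %>%
    count(category = .data$category, name = "count")
  eff_counts <- annotations %>%
    filter(.data$category == "exonic") %>%
    count(effect = .data$exonic_effect, name = "count") %>%
    mutate(category = "exonic")
  category_summary_from_counts(bind_rows(
    cat_counts %>% filter(.data$category != "exonic"),
    eff_counts
  ))
}

#' Build a category summary from pre-tabulated counts
#'
#' Accepts a tibble of per-category counts -- the layout of a printed
#' annotation summary table -- with optional exonic-effect breakdown rows
#' (`category == "exonic"` with a non-missing `effect`). When no exonic
#' total row is given it is derived as the sum of the breakdown rows. The
#' annotated total is the sum of the category-level counts.
#'
#' @param counts Tibble with columns `category`, `count` and optionally
#'   `effect`.
#' @return A `category_summary` tibble; see [summarize_categories()].
#' @export
category_summary_from_counts <- function(counts) {
  if (!"effect" %in% names(counts)) counts$effect <- NA_character_
  breakdown <- counts %>%
    filter(.data$category == "exonic", !is.na(.data$effect))
  plain <- counts %>%
    filter(!(.data$category == "exonic" & !is.na(.data$effect)))
  if (!"exonic" %in% plain$category && nrow(breakdown) > 0) {
    plain <- bind_rows(
      plain,
      tibble(
        category = "exonic", count = sum(breakdown$count),
        effect = NA_character_
      )
    )
  }
  total <- sum(plain$count)
  plain <- plain %>%
    mutate(percentage = round_half_up(100 * .data$count / total, 2))
  breakdown <- breakdown %>% mutate(percentage = NA_real_)
  out <- bind_rows(plain, breakdown) %>%
    mutate(
      cat_rank = match(.data$category, ANNOTATION_CATEGORIES),
      eff_rank = match(.data$effect, EXONIC_EFFECTS)
    ) %>%
    arrange(!is.na(.data$effect), .data$cat_rank, .data$eff_rank) %>%
    select("category", "effect", "count", "percentage")
  attr(out, "total_annotated") <- total
  class(out) <- c("category_summary", class(out))
  out
}
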