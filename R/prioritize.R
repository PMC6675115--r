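#' Interpolate a physical position onto the genetic map
#'
#' Piecewise-linear interpolation between the flanking (bp, cM) anchors of
#' the chromosome; exact at anchors. Positions beyond the terminal anchors
#' are extrapolated with the terminal segment's slope, so the mapping is
#' defined (and monotone) over the whole chromosome.
#'
#' @param map Genetic-map anchor tibble (see [read_genetic_map()]).
#' @param chromosome Chromosome id (must be present in the map).
#' @param bp Physical position(s), 1-based; vectorized.
#' @return Genetic position(s) in cM.
#' @examples
#' map <- tibble::tibble(
#'   chromosome = "chr1", bp = c(1e6, 2e6), cM = c(1, 3)
#' )
#' interpolate_cm(map, "chr1", 1.5e6) # 2.0
#' @export
interpolate_cm <- function(map, chromosome, bp) {
  anchors <- map %>%
    filter(.data$chromosome == !!chromosome) %>%
    arrange(.data$bp)
  if (nrow(anchors) < 2) {
    stop_bad_arg(sprintf(
      "chromosome `%s` has fewer than two genetic-map anchors", chromosome
    ))
  }
  i <- findInterval(bp, anchors$bp)
  i <- pmin(pmax(i, 1L), nrow(anchors) - 1L)
  slope <- (anchors$cM[i + 1] - anchors$cM[i]) /
    (anchors$bp[i + 1] - anchors$bp[i])
  anchors$cM[i] + (bp - anchors$bp[i]) * slope
}

#' Distance from a gene to the nearest QTL peak
#'
#' Minimum absolute cM distance between a gene's map position and the peaks
#' of the QTL records on its chromosome (after trait filtering). Selection
#' downstream always uses the unrounded distance; the half-up one-decimal
#' rounding is provided for display.
#'
#' @param gene_cm Gene position in cM.
#' @param qtls QTL tibble (see [read_qtl_table()]).
#' @param chromosome Chromosome id of the gene.
#' @param traits Trait codes to keep (`NULL` keeps all).
#' @return A one-row tibble: `distance_cm` (unrounded; `NA` when no QTL
#'   lies on the chromosome), `distance_cm_1dp`, `peak_cm`, `trait`,
#'   `ci_start_cM`, `ci_end_cM`, `source`.
#' @examples
#' qtls <- tibble::tibble(
#'   chromosome = "chr7", trait = "PP", ci_start_cM = 15.2, ci_end_cM = 38.5,
#'   peaks = list(c(17.8, 15.9)), source = "x"
#' )
#' qtl_min_distance(17.9, qtls, "chr7")$distance_cm_1dp # 0.1
#' @export
qtl_min_distance <- function(gene_cm, qtls, chromosome, traits = NULL) {
  cand <- qtls %>% filter(.data$chromosome == !!chromosome)
  if (!is.null(traits)) cand <- cand %>% filter(.data$trait %in% traits)
  no_qtl <- tibble(
    distance_cm = NA_real_, distance_cm_1dp = NA_real_, peak_cm = NA_real_,
    trait = NA_character_, ci_start_cM = NA_real_, ci_end_cM = NA_real_,
    source = NA_character_
  )
  if (nrow(cand) == 0) {
    return(no_qtl)
  }
  flat <- cand %>%
    mutate(row = row_number()) %>%
    tidyr::unnest_longer("peaks", values_to = "peak_cm") %>%
    mutate(distance_cm = abs(gene_cm - .data$peak_cm)) %>%
    arrange(.data$distance_cm, .data$row, .data$peak_cm)
  best <- flat[1, ]
  tibble(
    distance_cm = best$distance_cm,
    distance_cm_1dp = round_half_up(best$distance_cm, 1),
    peak_cm = best$peak_cm,
    trait = best$trait,
    ci_start_cM = best$ci_start_cM,
    ci_end_cM = best$ci_end_cM,
    source = best$source
  )
}

#' Select candidate genes
#'
#' Applies the three retention rules jointly: a gene is a candidate iff (a)
#' it is in the trait-relevant functional gene set, (b) its unrounded
#' minimum QTL-peak distance for a configured trait is strictly below
#' `qtl_max_cm`, and (c) it has at least one attached common differential
#' SNV in a qualifying category (exonic, UTR or up/downstream; intronic or
#' intergenic support alone does not qualify).
#'
#' @param functional_genes Tibble from [select_functional_genes()].
#' @param attachments SNV-gene assignments from [attach_to_genes()].
#' @param annotations Annotation tibble from [assign_category()].
#' @param genes Gene tibble.
#' @param map Genetic-map tibble.
#' @param qtls QTL tibble.
#' @param config A [pipeline_config()].
#' @return Candidate tibble sorted by chromosome then gene start: gene,
#'   span, map position, provenance, supporting SNVs (position, category
#'   and high/low alleles, semicolon-joined), and the nearest QTL with its
#'   unrounded and display distances.
#' @export
select_candidates <- function(functional_genes, attachments, annotations,
                              genes, map, qtls,
                              config = pipeline_config()) {
  empty <- tibble(
    gene_id = character(), chromosome = character(),
    gene_start = integer(), gene_end = integer(), gene_cm = numeric(),
    admitted_by = character(), n_support = integer(),
    support_snvs = character(), qtl_trait = character(),
    qtl_peak_cm = numeric(), qtl_distance_cm = numeric(),
    qtl_distance_cm_1dp = numeric(), qtl_source = character()
  )
  if (nrow(functional_genes) == 0 || nrow(attachments) == 0) {
    return(empty)
  }
  support <- attachments %>%
    inner_join(
      annotations %>%
        select("chromosome", "position", "ref", "alt", "category"),
      by = c("chromosome", "position", "ref", "alt")
    ) %>%
    filter(.data$category %in% QUALIFYING_CATEGORIES) %>%
    semi_join(functional_genes, by = "gene_id")
  if (nrow(support) == 0) {
    return(empty)
  }
  gene_rows <- genes %>%
    semi_join(support, by = "gene_id") %>%
    inner_join(functional_genes, by = "gene_id")
  out <- lapply(seq_len(nrow(gene_rows)), function(i) {
    g <- gene_rows[i, ]
    pos_bp <- if (config$gene_position == "midpoint") {
      (g$start + g$end) / 2
    } else {
      g$start
    }
    gene_cm <- interpolate_cm(map, g$chromosome, pos_bp)
    qtl <- qtl_min_distance(gene_cm, qtls, g$chromosome, config$traits)
    if (is.na(qtl$distance_cm) || qtl$distance_cm >= config$qtl_max_cm) {
      return(NULL)
    }
    sup <- support %>%
      filter(.data$gene_id == g$gene_id) %>%
      arrange(.data$position)
    tibble(
      gene_id = g$gene_id, chromosome = g$chromosome,
      gene_start = g$start, gene_end = g$end, gene_cm = gene_cm,
      admitted_by = g$admitted_by, n_support = nrow(sup),
      support_snvs = paste(sprintf(
        "%d:%s:%s>%s", sup$position, sup$category,
        sup$high_allele, sup$low_allele
      ), collapse = ";"),
      qtl_trait = qtl$trait, qtl_peak_cm = qtl$peak_cm,
      qtl_distance_cm = qtl$distance_cm,
      qtl_distance_cm_1dp = qtl$distance_cm_1dp,
      qtl_source = qtl$source
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(empty)
  }
  res %>% arrange(chrom_rank(.data$chromosome), .data$gene_start)
}
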