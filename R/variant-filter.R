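#' SNV call acceptance filter
#'
#' Applies the per-call quality thresholds to a tibble of call records: a
#' variant call passes iff base quality >= `min_base_quality`, read depth is
#' strictly below `max_depth_exclusive`, and the number of alt-supporting
#' reads is strictly greater than `min_alt_reads_exclusive` (i.e. >= 4 under
#' the defaults). Missing genotypes never pass. Explicit
#' homozygous-reference records assert the absence of the variant and carry
#' no alt reads, so only the base-quality and depth thresholds apply to
#' them.
#'
#' @param calls Call tibble with columns `genotype`, `base_quality`,
#'   `depth`, `alt_reads` (see [read_vcf_calls()]).
#' @param config A [pipeline_config()].
#' @return Logical vector, one element per record.
#' @examples
#' calls <- tibble::tibble(
#'   genotype = c("hom_alt", "het", "hom_alt"),
#'   base_quality = c(20, 19, 35), depth = c(99, 50, 100),
#'   alt_reads = c(4, 10, 20)
#' )
#' passes_call_filters(calls, pipeline_config())
#' @export
passes_call_filters <- function(calls, config = pipeline_config()) {
  core <- !is.na(calls$base_quality) & !is.na(calls$depth) &
    calls$base_quality >= config$min_base_quality &
    calls$depth < config$max_depth_exclusive
  variant <- calls$genotype %in% c("het", "hom_alt")
  alt_ok <- !is.na(calls$alt_reads) &
    calls$alt_reads > config$min_alt_reads_exclusive
  pass <- core & (!variant | alt_ok)
  pass[calls$genotype == "missing"] <- FALSE
  pass
}

#' Assemble a cross-sample genotype matrix from per-sample VCFs
#'
#' Reads every sample's VCF, applies [passes_call_filters()] (records that
#' fail are demoted to `missing`), takes the union of sites across samples,
#' and returns a site-by-sample genotype table. A sample with no record at a
#' union site is recorded according to `config$absent_means`: `"missing"`
#' (default; a single-sample VCF cannot distinguish "reference" from "no
#' data") or `"hom_ref"`. An explicit homozygous-reference record applies to
#' every alternate allele observed at its position. Positions reported with
#' conflicting reference alleles raise an error; positions with more than
#' two distinct alternate alleles across samples are dropped with a
#' warning.
#'
#' @param vcf_paths Character vector of VCF paths (each file may carry one
#'   or more samples; together they must cover every design sample).
#' @param design Family design tibble or CSV path (see
#'   [read_family_design()]).
#' @param config A [pipeline_config()].
#' @return A tibble with columns `chromosome`, `position`, `ref`, `alt`
#'   followed by one genotype-state column per sample (family order: high,
#'   low), sorted by chromosome (natural order) then position. The sample
#'   ids are attached as attribute `"samples"`.
#' @export
build_genotype_matrix <- function(vcf_paths, design,
                                  config = pipeline_config()) {
  if (is.character(design)) design <- read_family_design(design)
  validate_family_design(design)
  samples <- as.vector(rbind(design$high_sample, design$low_sample))

  calls <- bind_rows(lapply(vcf_paths, read_vcf_calls))
  have <- unique(calls$sample)
  absent <- setdiff(samples, have)
  if (length(absent) > 0) {
    stop_bad_arg(paste0(
      "design samples without VCF records: ", paste(absent, collapse = ", ")
    ))
  }
  calls <- calls %>% filter(.data$sample %in% samples)

  ref_conflict <- calls %>%
    distinct(.data$chromosome, .data$position, .data$ref) %>%
    count(.data$chromosome, .data$position) %>%
    filter(.data$n > 1)
  if (nrow(ref_conflict) > 0) {
    stop_bad_arg(sprintf(
      "conflicting reference alleles at %s:%d",
      ref_conflict$chromosome[1], ref_conflict$position[1]
    ))
  }

  n_alts <- calls %>%
    distinct(.data$chromosome, .data$position, .data$alt) %>%
    count(.data$chromosome, .data$position, name = "n_alt")
  too_many <- n_alts %>% filter(.data$n_alt > 2)
  if (nrow(too_many) > 0) {
    warn(sprintf(
      "dropping %d position(s) with more than two alternate alleles",
      nrow(too_many)
    ))
    calls <- calls %>%
      anti_join(too_many, by = c("chromosome", "position"))
  }

  calls <- calls %>%
    mutate(genotype = ifelse(
      passes_call_filters(calls, config), .data$genotype, "missing"
    )) %>%
    filter(.data$genotype != "missing")

  sites <- calls %>%
    distinct(.data$chromosome, .data$position, .data$ref, .data$alt)

  # a hom_ref record asserts the reference state for every alt observed
  # at its position
  hom_ref <- calls %>%
    filter(.data$genotype == "hom_ref") %>%
    distinct(.data$chromosome, .data$position, .data$sample) %>%
    inner_join(sites, by = c("chromosome", "position")) %>%
    mutate(genotype = "hom_ref")
  variant <- calls %>%
    filter(.data$genotype != "hom_ref") %>%
    select(
      "chromosome", "position", "ref", "alt", "sample", "genotype"
    )
  states <- bind_rows(variant, hom_ref) %>%
    distinct(
      .data$chromosome, .data$position, .data$ref, .data$alt, .data$sample,
      .keep_all = TRUE
    )

  gm <- states %>%
    tidyr::pivot_wider(
      id_cols = c("chromosome", "position", "ref", "alt"),
      names_from = "sample", values_from = "genotype",
      values_fill = config$absent_means
    )
  for (s in setdiff(samples, names(gm))) gm[[s]] <- config$absent_means
  gm <- gm %>%
    select("chromosome", "position", "ref", "alt", all_of(samples)) %>%
    arrange_sites()
  attr(gm, "samples") <- samples
  gm
}
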