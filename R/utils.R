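#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when printing category
#' percentages and map distances. Base R's `round()` rounds half to even,
#' which prints 0.125 as 0.12; summary tables here follow the half-up
#' convention instead.
#'
#' @param x Numeric vector (non-negative values expected).
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.125, 78.695), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon guards against binary representation of exact halves
  floor(x * p + 0.5 + 1e-9) / p
}

#' Natural ordering rank for chromosome identifiers
#'
#' Orders "chr2" before "chr10"; purely alphabetic identifiers sort after
#' numbered ones, lexicographically.
#'
#' @param chrom Character vector of chromosome ids.
#' @return Integer rank usable as a sort key.
#' @export
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z_]*", "", u)))
  ord <- order(is.na(num), num, u)
  match(chrom, u[ord])
}

# sort a site-keyed tibble by natural chromosome order then position
arrange_sites <- function(df) {
  df %>%
    arrange(chrom_rank(.data$chromosome), .data$position)
}

GENOTYPE_STATES <- c("hom_ref", "het", "hom_alt", "missing")

ANNOTATION_CATEGORIES <- c(
  "exonic", "UTR5", "UTR3", "intronic", "ncRNA_exonic", "ncRNA_intronic",
  "upstream", "downstream", "upstream;downstream", "intergenic"
)

EXONIC_EFFECTS <- c(
  "nonsynonymous", "synonymous", "stopgain", "stoploss", "unknown",
  "not_applicable"
)

# categories counted as regulatory/coding support for candidate genes
QUALIFYING_CATEGORIES <- c(
  "exonic", "UTR5", "UTR3", "upstream", "downstream", "upstream;downstream"
)

DNA_BASES <- c("A", "C", "G", "T")

stop_bad_arg <- function(msg) abort(msg, class = "extremediff_error")

# sample() treats a length-1 numeric as 1:x; this does not
sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)
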