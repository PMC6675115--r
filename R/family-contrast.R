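allele_of <- function(state, ref, alt) {
  ifelse(state == "hom_ref", ref, ifelse(state == "hom_alt", alt, NA_character_))
}

#' Within-family opposite-fixed sites
#'
#' Scans the genotype matrix for sites at which one sib pair is fixed for
#' opposite alleles: the high-breeding-value sample homozygous for one
#' allele and the low sample homozygous for a different allele.
#' Heterozygous or missing states disqualify a site. With
#' `polymorphic_only = TRUE` the looser intermediate list is returned
#' instead: every site at which the two samples have different (non-missing)
#' genotypes, for inspection; the fixed-opposite set is its subset.
#'
#' @param gm Genotype matrix from [build_genotype_matrix()].
#' @param high_sample,low_sample Column names of the pair.
#' @param polymorphic_only Return the polymorphic-pair list instead of the
#'   fixed-opposite list.
#' @return A tibble of qualifying sites: `chromosome`, `position`, `ref`,
#'   `alt` plus `high_allele`/`low_allele` (or `high_state`/`low_state`
#'   when `polymorphic_only`), sorted by chromosome then position.
#' @export
family_differential <- function(gm, high_sample, low_sample,
                                polymorphic_only = FALSE) {
  for (s in c(high_sample, low_sample)) {
    if (!s %in% names(gm)) {
      stop_bad_arg(sprintf("sample `%s` is not in the genotype matrix", s))
    }
  }
  hs <- gm[[high_sample]]
  ls <- gm[[low_sample]]
  keys <- gm %>% select("chromosome", "position", "ref", "alt")
  if (polymorphic_only) {
    keep <- hs != "missing" & ls != "missing" & hs != ls
    out <- keys[keep, ]
    out$high_state <- hs[keep]
    out$low_state <- ls[keep]
    return(arrange_sites(out))
  }
  ha <- allele_of(hs, gm$ref, gm$alt)
  la <- allele_of(ls, gm$ref, gm$alt)
  keep <- !is.na(ha) & !is.na(la) & ha != la
  out <- keys[keep, ]
  out$high_allele <- ha[keep]
  out$low_allele <- la[keep]
  arrange_sites(out)
}

#' Common differential SNVs across families
#'
#' Intersects the per-family opposite-fixed site lists over the whole
#' design, requiring a consistent orientation: a site is a common
#' differential SNV iff every high sample is homozygous for the same allele
#' A, every low sample is homozygous for the same allele B, and A != B. A
#' single heterozygous or missing state anywhere excludes the site.
#'
#' @param gm Genotype matrix from [build_genotype_matrix()].
#' @param design Family design tibble or CSV path.
#' @return A tibble of common differential SNVs: `chromosome`, `position`,
#'   `ref`, `alt`, `high_allele`, `low_allele`, `n_families`, sorted by
#'   chromosome (natural order) then position.
#' @export
common_differential <- function(gm, design) {
  if (is.character(design)) design <- read_family_design(design)
  validate_family_design(design)
  fams <- lapply(seq_len(nrow(design)), function(i) {
    family_differential(gm, design$high_sample[i], design$low_sample[i])
  })
  out <- purrr::reduce(fams, function(a, b) {
    inner_join(a, b, by = c(
      "chromosome", "position", "ref", "alt", "high_allele", "low_allele"
    ))
  })
  out %>%
    mutate(n_families = nrow(design)) %>%
    arrange_sites()
}
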