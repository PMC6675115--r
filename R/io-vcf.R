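vcf_header <- function(contig_lengths, samples) {
  c(
    "##fileformat=VCFv4.2",
    "##source=extremediff",
    sprintf(
      "##contig=<ID=%s,length=%d>",
      names(contig_lengths), as.integer(contig_lengths)
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0(
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
      "\"Allelic depths for the ref and alt alleles\">"
    ),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(
      c(
        "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", samples
      ),
      collapse = "\t"
    )
  )
}

gt_string <- function(genotype) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[genotype]
}

#' Write per-sample and cohort VCF files
#'
#' `write_sample_vcf()` writes one sample's call records (including explicit
#' homozygous-reference records) as a single-sample VCFv4.2 file with
#' `FORMAT GT:AD:DP`; the site QUAL column carries the per-call base
#' quality. `write_cohort_vcf()` writes the merged multi-sample convenience
#' VCF; its QUAL is the rounded mean base quality over samples with a
#' record, and samples without a record at a site are emitted as `./.`.
#' Both writers are byte-deterministic for a fixed input.
#'
#' @param calls Long call tibble: `chromosome`, `position`, `ref`, `alt`,
#'   `sample`, `genotype`, `base_quality`, `depth`, `alt_reads`.
#' @param sample Sample id to write (must appear in `calls$sample`).
#' @param samples Column order for the cohort file.
#' @param path Output file.
#' @param contig_lengths Named vector of chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(calls, sample, path, contig_lengths) {
  rec <- calls %>%
    filter(.data$sample == !!sample, .data$genotype != "missing") %>%
    arrange_sites()
  ref_reads <- rec$depth - rec$alt_reads
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%d\tPASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
    rec$chromosome, rec$position, rec$ref, rec$alt,
    as.integer(rec$base_quality), gt_string(rec$genotype),
    as.integer(ref_reads), as.integer(rec$alt_reads), as.integer(rec$depth)
  )
  writeLines(c(vcf_header(contig_lengths, sample), body), path)
  invisible(path)
}

#' @rdname write_sample_vcf
#' @export
write_cohort_vcf <- function(calls, samples, path, contig_lengths) {
  sites <- calls %>%
    distinct(.data$chromosome, .data$position, .data$ref, .data$alt) %>%
    arrange_sites()
  present <- calls %>% filter(.data$genotype != "missing")
  qual <- present %>%
    group_by(.data$chromosome, .data$position) %>%
    summarise(qual = round(mean(.data$base_quality)), .groups = "drop")
  wide <- present %>%
    mutate(cell = sprintf(
      "%s:%d,%d:%d", gt_string(.data$genotype),
      as.integer(.data$depth - .data$alt_reads), as.integer(.data$alt_reads),
      as.integer(.data$depth)
    )) %>%
    select("chromosome", "position", "ref", "alt", "sample", "cell") %>%
    tidyr::pivot_wider(
      names_from = "sample", values_from = "cell", values_fill = "./."
    )
  for (s in setdiff(samples, names(wide))) wide[[s]] <- "./."
  sites <- sites %>%
    left_join(qual, by = c("chromosome", "position")) %>%
    left_join(wide, by = c("chromosome", "position", "ref", "alt"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(
      c(
        sites$chromosome[i], sites$position[i], ".", sites$ref[i],
        sites$alt[i], as.integer(sites$qual[i]), "PASS", ".", "GT:AD:DP",
        unlist(sites[i, samples], use.names = FALSE)
      ),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(vcf_header(contig_lengths, samples), body), path)
  invisible(path)
}

#' Read SNV call records from a VCF file
#'
#' Parses a (single- or multi-sample) VCFv4.2 file into the long call-record
#' tibble used by [build_genotype_matrix()]. The site QUAL column is taken
#' as the per-call base-quality surrogate; depth comes from `DP` and
#' alt-supporting reads from `AD`. Multi-allelic records are split into one
#' biallelic record per alternate allele: a genotype carrying two copies of
#' that allele maps to `hom_alt`, one copy to `het`, none to `hom_ref` when
#' the genotype is fully reference and to `missing` otherwise.
#'
#' @param path VCF file (plain or bgzipped).
#' @return Long call tibble: `chromosome`, `position`, `ref`, `alt`,
#'   `sample`, `genotype`, `base_quality`, `depth`, `alt_reads`.
#' @export
read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  samples <- colnames(gt)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  alt_split <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  multi <- lengths(alt_split) > 1L
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    # vectorized fast path for biallelic records
    bi <- which(!multi)
    gstr <- gt[bi, si]
    genotype <- case_when(
      is.na(gstr) ~ "missing",
      gstr %in% c("0/0", "0|0") ~ "hom_ref",
      gstr %in% c("0/1", "1/0", "0|1", "1|0") ~ "het",
      gstr %in% c("1/1", "1|1") ~ "hom_alt",
      TRUE ~ "missing"
    )
    ad_bi <- ad[bi, si]
    alt_reads <- suppressWarnings(as.numeric(sub("^[^,]*,", "", ad_bi)))
    bi_tb <- tibble(
      chromosome = fix[bi, "CHROM"],
      position = as.integer(fix[bi, "POS"]),
      ref = fix[bi, "REF"],
      alt = unlist(alt_split[bi], use.names = FALSE),
      sample = s,
      genotype = genotype,
      base_quality = qual[bi],
      depth = dp[bi, si],
      alt_reads = alt_reads
    )
    mu_tb <- lapply(which(multi), function(i) {
      alts <- alt_split[[i]]
      g <- gt[i, si]
      alleles <- if (is.na(g) || g %in% c(".", "./.", ".|.")) {
        NULL
      } else {
        suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      }
      ad_vec <- if (!is.na(ad[i, si])) {
        suppressWarnings(as.numeric(strsplit(ad[i, si], ",", fixed = TRUE)[[1]]))
      } else {
        rep(NA_real_, length(alts) + 1L)
      }
      tibble(
        chromosome = fix[i, "CHROM"],
        position = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts,
        sample = s,
        genotype = vapply(seq_along(alts), function(j) {
          if (is.null(alleles) || anyNA(alleles)) {
            return("missing")
          }
          copies <- sum(alleles == j)
          if (copies == 2L) {
            "hom_alt"
          } else if (copies == 1L) {
            "het"
          } else if (all(alleles == 0L)) {
            "hom_ref"
          } else {
            "missing"
          }
        }, character(1)),
        base_quality = qual[i],
        depth = dp[i, si],
        alt_reads = ad_vec[seq_along(alts) + 1L]
      )
    })
    out[[si]] <- bind_rows(bi_tb, bind_rows(mu_tb))
  }
  bind_rows(out) %>% arrange_sites()
}
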