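#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: genome size, gene complement, cohort
#' variant load, planted ground truth, and per-call noise. Defaults emulate
#' a small desk-scale analogue of an eight-bull, four-family resequencing
#' design: 8 diploid samples (one high- and one low-breeding-value sib per
#' family), biallelic SNVs with per-call base quality, depth and
#' alt-supporting read counts.
#'
#' @param n_chromosomes Number of simulated chromosomes.
#' @param chromosome_length_bp Length of each chromosome in bp.
#' @param n_genes Total genes placed (non-overlapping, separated by at least
#'   12 kb so the 1 kb / 5 kb distance classes are unambiguous).
#' @param fraction_noncoding_genes Fraction of genes given an ncRNA biotype;
#'   the count is `round(fraction * n_genes)`, exactly.
#' @param n_background_snvs Background SNVs whose genotypes are drawn
#'   independently of the high/low group labels (and are constrained never to
#'   form an opposite-fixed pattern, so planted truth stays exact).
#' @param n_planted_differential Sites planted homozygous for one allele in
#'   all high samples and for the other allele in all low samples.
#' @param n_planted_candidate_genes Genes given one planted differential SNV
#'   in a qualifying region (exonic/UTR/up/downstream) plus a supporting
#'   enriched gene set and a QTL peak within 1 cM; must not exceed
#'   `n_planted_differential`.
#' @param het_rate Per-sample heterozygote probability at background sites.
#' @param missing_rate Probability that a (site, sample) call record is
#'   omitted from that sample's VCF.
#' @param depth_mean Mean sequencing depth (Poisson) for call records.
#' @param base_quality_mean Mean phred base quality written as site QUAL.
#' @param filter_fail_rate Fraction of emitted call records deliberately
#'   given metrics that fail the call-acceptance thresholds (quality < 20,
#'   depth >= 100, or <= 3 alt reads).
#' @param seed Integer seed; all draws derive from it and outputs are
#'   byte-reproducible for a fixed value.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 20, n_background_snvs = 200, seed = 7)
#' cfg$n_genes
#' @export
sim_config <- function(n_chromosomes = 5,
                       chromosome_length_bp = 1e6,
                       n_genes = 60,
                       fraction_noncoding_genes = 0.1,
                       n_background_snvs = 2000,
                       n_planted_differential = 50,
                       n_planted_candidate_genes = 5,
                       het_rate = 0.3,
                       missing_rate = 0.02,
                       depth_mean = 8,
                       base_quality_mean = 30,
                       filter_fail_rate = 0.05,
                       seed = 1) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    n_genes = as.integer(n_genes),
    fraction_noncoding_genes = fraction_noncoding_genes,
    n_background_snvs = as.integer(n_background_snvs),
    n_planted_differential = as.integer(n_planted_differential),
    n_planted_candidate_genes = as.integer(n_planted_candidate_genes),
    het_rate = het_rate,
    missing_rate = missing_rate,
    depth_mean = depth_mean,
    base_quality_mean = base_quality_mean,
    filter_fail_rate = filter_fail_rate,
    seed = as.integer(seed)
  )
  counts <- c(
    "n_chromosomes", "chromosome_length_bp", "n_genes",
    "n_background_snvs", "depth_mean", "base_quality_mean"
  )
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop_bad_arg(sprintf("`%s` must be a positive count", f))
    }
  }
  for (f in c("n_planted_differential", "n_planted_candidate_genes")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop_bad_arg(sprintf("`%s` must be a non-negative count", f))
    }
  }
  props <- c(
    "fraction_noncoding_genes", "het_rate", "missing_rate",
    "filter_fail_rate"
  )
  for (f in props) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_bad_arg(sprintf("`%s` must be a proportion in [0, 1]", f))
    }
  }
  if (cfg$n_planted_candidate_genes > cfg$n_genes) {
    stop_bad_arg("`n_planted_candidate_genes` cannot exceed `n_genes`")
  }
  if (cfg$n_planted_differential < cfg$n_planted_candidate_genes) {
    stop_bad_arg(
      "`n_planted_differential` must be at least `n_planted_candidate_genes`"
    )
  }
  structure(cfg, class = "sim_config")
}

#' Pipeline configuration: thresholds, windows and selection rules
#'
#' Collects every tunable of the analysis. Defaults are the published study
#' conditions: call acceptance at base quality >= 20, depth < 100 and > 3
#' alt-supporting reads; near-gene (up/downstream) window of 1 kb; gene
#' attachment window of 5 kb; raw Fisher/hypergeometric P < 0.05 for
#' over-representation; QTL-peak proximity < 1 cM; the eight named
#' metabolism pathways as the whitelist.
#'
#' @param min_base_quality Minimum phred base quality (inclusive).
#' @param max_depth_exclusive Read-depth ceiling; depth must be strictly
#'   below this value.
#' @param min_alt_reads_exclusive Alt-supporting read floor; variant records
#'   need strictly more than this many alt reads. Not applied to explicit
#'   homozygous-reference records, which carry no alt reads by definition.
#' @param near_gene_bp Up/downstream window (bp, boundary-inclusive); sites
#'   farther than this from every gene are intergenic.
#' @param gene_window_bp Gene-attachment window (bp, boundary-inclusive) for
#'   downstream gene-level analyses.
#' @param ora_alpha Significance level for raw over-representation P values.
#' @param qtl_max_cm QTL-peak proximity bound (cM, strict: distance must be
#'   `< qtl_max_cm` on the unrounded value).
#' @param whitelist_pathways Pathway labels whose member genes are retained
#'   regardless of enrichment significance (case-insensitive substring
#'   match against gene-set labels).
#' @param relevance_keywords Keywords selecting significant gene sets whose
#'   member genes are considered trait-relevant (case-insensitive substring
#'   match).
#' @param traits QTL trait codes considered (milk protein/fat percentage and
#'   yield by default).
#' @param gene_position How a gene is reduced to one map position:
#'   `"start"` (span start) or `"midpoint"`.
#' @param absent_means Interpretation of a sample lacking any record at a
#'   site other samples report: `"missing"` (unknowable; default) or
#'   `"hom_ref"`.
#' @param bh_correction Apply Benjamini-Hochberg correction to
#'   over-representation P values before the significance call (off by
#'   default: the selection criterion is the raw P).
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_base_quality
#' @export
pipeline_config <- function(min_base_quality = 20,
                            max_depth_exclusive = 100,
                            min_alt_reads_exclusive = 3,
                            near_gene_bp = 1000,
                            gene_window_bp = 5000,
                            ora_alpha = 0.05,
                            qtl_max_cm = 1.0,
                            whitelist_pathways = c(
                              "mTOR", "insulin", "AMPK", "PPAR", "Jak-STAT",
                              "PI3K-Akt", "MAPK", "TGF-β"
                            ),
                            relevance_keywords = c(
                              "protein", "lipid", "fatty acid", "amino acid",
                              "fat", "insulin"
                            ),
                            traits = c("PP", "PY", "FP", "FY"),
                            gene_position = c("start", "midpoint"),
                            absent_means = c("missing", "hom_ref"),
                            bh_correction = FALSE) {
  gene_position <- match.arg(gene_position)
  absent_means <- match.arg(absent_means)
  cfg <- list(
    min_base_quality = min_base_quality,
    max_depth_exclusive = max_depth_exclusive,
    min_alt_reads_exclusive = min_alt_reads_exclusive,
    near_gene_bp = near_gene_bp,
    gene_window_bp = gene_window_bp,
    ora_alpha = ora_alpha,
    qtl_max_cm = qtl_max_cm,
    whitelist_pathways = whitelist_pathways,
    relevance_keywords = relevance_keywords,
    traits = traits,
    gene_position = gene_position,
    absent_means = absent_means,
    bh_correction = bh_correction
  )
  thresholds <- c(
    "min_base_quality", "max_depth_exclusive", "min_alt_reads_exclusive",
    "near_gene_bp", "gene_window_bp", "qtl_max_cm"
  )
  for (f in thresholds) {
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop_bad_arg(sprintf("`%s` must be a positive number", f))
    }
  }
  if (!is.numeric(ora_alpha) || ora_alpha <= 0 || ora_alpha >= 1) {
    stop_bad_arg("`ora_alpha` must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}
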