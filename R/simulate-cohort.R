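#' Simulate the eight-sample, four-family cohort
#'
#' Plants `n_planted_differential` opposite-fixed sites -- homozygous for
#' one allele in all four high samples and for the other allele in all four
#' low samples -- of which the first `n_planted_candidate_genes` fall in
#' qualifying regions (exonic, UTR, up/downstream; cycled) of the planted
#' candidate genes; the remainder alternate between introns of
#' non-candidate coding genes and deep intergenic space (more than 6 kb
#' from every gene). Background SNVs receive genotypes independently of the
#' group labels and are constrained never to form an opposite-fixed
#' pattern, so the planted truth is exactly recoverable. Per-call metrics
#' (site QUAL as base quality, DP, alt-supporting AD) are drawn from
#' threshold-passing ranges; a `filter_fail_rate` fraction of records is
#' deliberately given failing metrics, and a `missing_rate` fraction of
#' (site, sample) records is omitted.
#'
#' Draws derive from `config$seed` (offset so the cohort is independent of
#' the reference draws); repeated calls are identical.
#'
#' @param config A [sim_config()].
#' @param reference,genes,features Output of [simulate_reference()].
#' @return A list: `calls` (long call tibble, see [read_vcf_calls()]),
#'   `design` (family design tibble), `samples` (column order),
#'   `truth_sites` (planted sites with alleles, intended category and gene)
#'   and `truth_genes` (planted candidate gene ids).
#' @export
simulate_cohort <- function(config, reference, genes, features) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(
    config$seed + 1L,
    simulate_cohort_impl(config, reference, genes, features)
  )
}

simulate_cohort_impl <- function(config, reference, genes, features) {
  design <- tibble(
    family_id = paste0("fam", 1:4),
    high_sample = paste0("high_", 1:4),
    low_sample = paste0("low_", 1:4)
  )
  highs <- design$high_sample
  lows <- design$low_sample
  samples <- as.vector(rbind(highs, lows))

  coding <- genes %>% filter(.data$biotype == "coding")
  n_cand <- config$n_planted_candidate_genes
  if (n_cand > nrow(coding)) {
    stop_bad_arg("not enough coding genes to host the planted candidates")
  }
  cand_genes <- sort(sample(coding$gene_id, n_cand))

  planted <- plant_sites(config, reference, genes, features, cand_genes)
  if (anyDuplicated(planted$position_key)) {
    stop_bad_arg("planted sites collide; enlarge the genome")
  }

  bg <- draw_background_sites(config, reference, genes, planted)

  sites <- bind_rows(
    planted %>% select(-"position_key"),
    bg
  ) %>% arrange_sites()
  n_sites <- nrow(sites)

  # genotype grid: sites x samples
  grid <- matrix("", nrow = n_sites, ncol = 8,
    dimnames = list(NULL, c(highs, lows))
  )
  for (i in seq_len(n_sites)) {
    if (sites$planted[i]) {
      high_state <- if (sites$high_allele[i] == sites$ref[i]) "hom_ref" else "hom_alt"
      low_state <- if (sites$low_allele[i] == sites$ref[i]) "hom_ref" else "hom_alt"
      grid[i, highs] <- high_state
      grid[i, lows] <- low_state
    } else {
      grid[i, ] <- draw_background_genotypes(config)
    }
  }

  calls <- tidyr::expand_grid(
    site = seq_len(n_sites), sample = c(highs, lows)
  ) %>%
    mutate(
      chromosome = sites$chromosome[.data$site],
      position = sites$position[.data$site],
      ref = sites$ref[.data$site],
      alt = sites$alt[.data$site],
      genotype = grid[cbind(.data$site, match(.data$sample, colnames(grid)))]
    ) %>%
    select(-"site")
  # drop records at the configured missing rate
  keep <- runif(nrow(calls)) >= config$missing_rate
  calls <- calls[keep, ]
  calls <- draw_call_metrics(calls, config)

  list(
    calls = calls %>% arrange_sites(),
    design = design,
    samples = samples,
    truth_sites = sites %>%
      filter(.data$planted) %>%
      select(
        "chromosome", "position", "ref", "alt", "high_allele", "low_allele",
        "intended_category", "gene_id"
      ),
    truth_genes = tibble(gene_id = cand_genes)
  )
}

# one planted site per candidate gene (qualifying categories, cycled),
# remainder split between intronic and deep-intergenic placements
plant_sites <- function(config, reference, genes, features, cand_genes) {
  qcats <- c("exonic", "UTR5", "UTR3", "upstream", "downstream")
  rows <- list()
  for (j in seq_along(cand_genes)) {
    g <- genes %>% filter(.data$gene_id == cand_genes[j])
    cat <- qcats[(j - 1L) %% length(qcats) + 1L]
    pos <- sample_position_in_category(g, features, cat)
    rows[[length(rows) + 1L]] <- tibble(
      chromosome = g$chromosome, position = pos,
      intended_category = cat, gene_id = g$gene_id
    )
  }
  n_other <- config$n_planted_differential - length(cand_genes)
  if (n_other > 0) {
    other_coding <- genes %>%
      filter(.data$biotype == "coding", !.data$gene_id %in% cand_genes)
    for (j in seq_len(n_other)) {
      if (j %% 2L == 1L && nrow(other_coding) > 0) {
        g <- other_coding[sample(nrow(other_coding), 1), ]
        pos <- sample_position_in_category(g, features, "intronic")
        rows[[length(rows) + 1L]] <- tibble(
          chromosome = g$chromosome, position = pos,
          intended_category = "intronic", gene_id = g$gene_id
        )
      } else {
        hit <- sample_intergenic_position(config, genes)
        rows[[length(rows) + 1L]] <- tibble(
          chromosome = hit$chromosome, position = hit$position,
          intended_category = "intergenic", gene_id = NA_character_
        )
      }
    }
  }
  planted <- bind_rows(rows)
  if (nrow(planted) == 0) {
    return(tibble(
      chromosome = character(), position = integer(), ref = character(),
      alt = character(), high_allele = character(), low_allele = character(),
      intended_category = character(), gene_id = character(),
      planted = logical(), position_key = character()
    ))
  }
  planted %>%
    mutate(
      ref = vapply(seq_len(dplyr::n()), function(i) {
        ref_bases(reference, .data$chromosome[i], .data$position[i])
      }, character(1)),
      alt = vapply(.data$ref, function(r) {
        sample(setdiff(DNA_BASES, r), 1)
      }, character(1)),
      high_is_ref = sample(c(TRUE, FALSE), dplyr::n(), replace = TRUE),
      high_allele = ifelse(.data$high_is_ref, .data$ref, .data$alt),
      low_allele = ifelse(.data$high_is_ref, .data$alt, .data$ref),
      planted = TRUE,
      position_key = paste(.data$chromosome, .data$position)
    ) %>%
    select(-"high_is_ref")
}

sample_position_in_category <- function(gene, features, category) {
  feats <- features %>% filter(.data$gene_id == gene$gene_id)
  pick_from_intervals <- function(iv) {
    if (nrow(iv) == 0) stop_bad_arg("gene lacks the requested feature")
    w <- iv$end - iv$start + 1L
    r <- sample.int(nrow(iv), 1, prob = w)
    sample_one(seq(iv$start[r], iv$end[r]))
  }
  switch(category,
    exonic = pick_from_intervals(feats %>% filter(.data$type == "CDS")),
    UTR5 = pick_from_intervals(feats %>% filter(.data$type == "five_prime_UTR")),
    UTR3 = pick_from_intervals(feats %>% filter(.data$type == "three_prime_UTR")),
    upstream = {
      if (gene$strand == "+") {
        gene$start - sample(1:1000, 1)
      } else {
        gene$end + sample(1:1000, 1)
      }
    },
    downstream = {
      if (gene$strand == "+") {
        gene$end + sample(1:1000, 1)
      } else {
        gene$start - sample(1:1000, 1)
      }
    },
    intronic = {
      ex <- feats %>% filter(.data$type == "exon") %>% arrange(.data$start)
      if (nrow(ex) < 2) stop_bad_arg("gene has no introns")
      r <- sample.int(nrow(ex) - 1L, 1)
      sample_one(seq(ex$end[r] + 1L, ex$start[r + 1L] - 1L))
    },
    stop_bad_arg(paste0("cannot plant category ", category))
  )
}

# a position more than 6 kb from every gene span (so it is neither
# near-gene nor attachable within the 5 kb window)
sample_intergenic_position <- function(config, genes) {
  for (attempt in 1:200) {
    chrom <- paste0("chr", sample.int(config$n_chromosomes, 1))
    pos <- sample(seq(1000L, config$chromosome_length_bp - 1000L), 1)
    g <- genes %>% filter(.data$chromosome == chrom)
    if (nrow(g) == 0 ||
      all(pos < g$start - 6000L | pos > g$end + 6000L)) {
      return(list(chromosome = chrom, position = pos))
    }
  }
  stop_bad_arg("could not place an intergenic site; genome too dense")
}

draw_background_sites <- function(config, reference, genes, planted) {
  n <- config$n_background_snvs
  if (n == 0) {
    return(tibble(
      chromosome = character(), position = integer(), ref = character(),
      alt = character(), high_allele = character(), low_allele = character(),
      intended_category = character(), gene_id = character(),
      planted = logical()
    ))
  }
  taken <- planted$position_key
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  out <- tibble(
    chromosome = sample(chroms, n, replace = TRUE),
    position = sample(
      seq(500L, config$chromosome_length_bp - 500L), n,
      replace = TRUE
    )
  ) %>%
    mutate(key = paste(.data$chromosome, .data$position)) %>%
    distinct(.data$key, .keep_all = TRUE) %>%
    filter(!.data$key %in% taken)
  while (nrow(out) < n) {
    extra <- tibble(
      chromosome = sample(chroms, n, replace = TRUE),
      position = sample(
        seq(500L, config$chromosome_length_bp - 500L), n,
        replace = TRUE
      )
    ) %>% mutate(key = paste(.data$chromosome, .data$position))
    out <- bind_rows(out, extra) %>%
      distinct(.data$key, .keep_all = TRUE) %>%
      filter(!.data$key %in% taken)
  }
  out <- out[seq_len(n), ]
  out %>%
    mutate(
      ref = vapply(seq_len(n), function(i) {
        ref_bases(reference, .data$chromosome[i], .data$position[i])
      }, character(1)),
      alt = vapply(.data$ref, function(r) {
        sample(setdiff(DNA_BASES, r), 1)
      }, character(1)),
      high_allele = NA_character_, low_allele = NA_character_,
      intended_category = NA_character_, gene_id = NA_character_,
      planted = FALSE
    ) %>%
    select(-"key")
}

# background genotypes: variant somewhere, never opposite-fixed
draw_background_genotypes <- function(config) {
  p_het <- config$het_rate
  p_hom_alt <- (1 - p_het) * 0.4
  probs <- c(1 - p_het - p_hom_alt, p_het, p_hom_alt)
  for (attempt in 1:50) {
    g <- sample(c("hom_ref", "het", "hom_alt"), 8, replace = TRUE, prob = probs)
    all_ref <- all(g == "hom_ref")
    opp <- length(unique(g[1:4])) == 1 && length(unique(g[5:8])) == 1 &&
      g[1] != g[5] && g[1] != "het" && g[5] != "het"
    if (!all_ref && !opp) {
      return(g)
    }
  }
  g[1] <- "het"
  g
}

# metrics drawn from threshold-passing ranges; a filter_fail_rate fraction
# of records is pushed outside one threshold
draw_call_metrics <- function(calls, config) {
  n <- nrow(calls)
  variant <- calls$genotype %in% c("het", "hom_alt")
  het <- calls$genotype == "het"

  bq <- pmin(pmax(round(rnorm(n, config$base_quality_mean, 4)), 20), 60)
  dp <- rpois(n, config$depth_mean)
  dp <- pmin(pmax(dp, ifelse(het, 9L, 5L)), 99L)
  ar <- integer(n)
  ar[calls$genotype == "hom_alt"] <- dp[calls$genotype == "hom_alt"]
  if (any(het)) {
    raw <- rbinom(sum(het), dp[het], 0.5)
    ar[het] <- pmin(pmax(raw, 4L), dp[het] - 4L)
  }

  fail <- runif(n) < config$filter_fail_rate
  if (any(fail)) {
    mode <- ifelse(
      variant, sample(1:3, n, replace = TRUE), sample(1:2, n, replace = TRUE)
    )
    i <- which(fail & mode == 1)
    bq[i] <- sample(5:19, length(i), replace = TRUE)
    i <- which(fail & mode == 2)
    dp[i] <- sample(100:150, length(i), replace = TRUE)
    ar[i] <- pmin(ar[i], dp[i])
    i <- which(fail & mode == 3)
    ar[i] <- sample(0:3, length(i), replace = TRUE)
  }

  calls$base_quality <- as.numeric(bq)
  calls$depth <- as.numeric(dp)
  calls$alt_reads <- as.numeric(ar)
  calls
}
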