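test_that("call filter thresholds sit exactly at the stated boundaries", {
  cfg <- pipeline_config()
  rec <- function(bq, dp, ar, gt = "hom_alt") {
    tibble::tibble(
      genotype = gt, base_quality = bq, depth = dp, alt_reads = ar
    )
  }
  # boundary record: quality 20, depth 99, 4 alt reads -> passes
  expect_true(passes_call_filters(rec(20, 99, 4), cfg))
  expect_false(passes_call_filters(rec(19, 50, 10), cfg))
  expect_false(passes_call_filters(rec(20, 100, 10), cfg)) # depth 100 fails
  expect_false(passes_call_filters(rec(20, 99, 3), cfg)) # >3 means >= 4
  # missing genotypes never pass
  expect_false(passes_call_filters(rec(60, 50, 40, gt = "missing"), cfg))
  # explicit hom_ref records are judged on quality and depth only
  expect_true(passes_call_filters(rec(20, 99, 0, gt = "hom_ref"), cfg))
  expect_false(passes_call_filters(rec(19, 99, 0, gt = "hom_ref"), cfg))
})

test_that("filter agrees with the per-record brute-force check on random records", {
  set.seed(41)
  n <- 1000
  recs <- tibble::tibble(
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
    base_quality = sample(10:40, n, replace = TRUE),
    depth = sample(1:130, n, replace = TRUE)
  )
  recs$alt_reads <- pmin(sample(0:20, n, replace = TRUE), recs$depth)
  got <- passes_call_filters(recs, pipeline_config())
  want <- logical(n)
  for (i in seq_len(n)) {
    want[i] <- recs$base_quality[i] >= 20 && recs$depth[i] < 100 &&
      recs$alt_reads[i] > 3
  }
  expect_equal(got, want)
  expect_equal(sum(got), sum(want))
})

test_that("tightening any threshold never increases the passing count", {
  set.seed(42)
  n <- 500
  recs <- tibble::tibble(
    genotype = sample(c("het", "hom_alt", "hom_ref"), n, replace = TRUE),
    base_quality = sample(10:40, n, replace = TRUE),
    depth = sample(1:130, n, replace = TRUE)
  )
  recs$alt_reads <- pmin(sample(0:20, n, replace = TRUE), recs$depth)
  base <- sum(passes_call_filters(recs, pipeline_config()))
  expect_lte(
    sum(passes_call_filters(recs, pipeline_config(min_base_quality = 25))),
    base
  )
  expect_lte(
    sum(passes_call_filters(recs, pipeline_config(max_depth_exclusive = 50))),
    base
  )
  expect_lte(
    sum(passes_call_filters(recs, pipeline_config(min_alt_reads_exclusive = 6))),
    base
  )
})

test_that("matrix assembly unifies identical single-site VCFs", {
  dir <- withr::local_tempdir()
  design <- fixture_design(4)
  samples <- as.vector(rbind(design$high_sample, design$low_sample))
  paths <- character(0)
  for (s in samples) {
    p <- file.path(dir, paste0(s, ".vcf"))
    write_fixture_vcf(p, s, vcf_record("chr1", 500, "A", "G", 35, "1/1", "0,12", 12))
    paths <- c(paths, p)
  }
  gm <- build_genotype_matrix(paths, design)
  expect_equal(nrow(gm), 1)
  expect_equal(unname(unlist(gm[1, samples])), rep("hom_alt", 8))
})

test_that("absent and filter-failing records become missing; hom_ref policy works", {
  dir <- withr::local_tempdir()
  design <- fixture_design(2)
  samples <- as.vector(rbind(design$high_sample, design$low_sample))
  # site 500 in all samples; site 900 missing from high_2, failing in low_2
  for (s in samples) {
    p <- file.path(dir, paste0(s, ".vcf"))
    recs <- vcf_record("chr1", 500, "A", "G", 35, "0/1", "6,6", 12)
    if (s == "low_2") {
      recs <- c(recs, vcf_record("chr1", 900, "C", "T", 10, "1/1", "0,9", 9))
    } else if (s != "high_2") {
      recs <- c(recs, vcf_record("chr1", 900, "C", "T", 30, "1/1", "0,9", 9))
    }
    write_fixture_vcf(p, s, recs)
  }
  paths <- file.path(dir, paste0(samples, ".vcf"))
  gm <- build_genotype_matrix(paths, design)
  row900 <- gm[gm$position == 900, ]
  expect_equal(row900$high_2, "missing") # no record, default policy
  expect_equal(row900$low_2, "missing") # quality 10 record demoted
  expect_equal(row900$high_1, "hom_alt")

  gm_ref <- build_genotype_matrix(
    paths, design, pipeline_config(absent_means = "hom_ref")
  )
  expect_equal(gm_ref[gm_ref$position == 900, ]$high_2, "hom_ref")
})

test_that("matrix assembly is invariant to VCF ordering and matches a re-parse", {
  cfg <- sim_config(
    n_chromosomes = 2, chromosome_length_bp = 4e5, n_genes = 12,
    n_background_snvs = 500, n_planted_differential = 10,
    n_planted_candidate_genes = 2, missing_rate = 0.05,
    filter_fail_rate = 0.1, seed = 7
  )
  dir <- withr::local_tempdir()
  sim <- simulate_study(cfg, dir)
  paths <- sim$paths$vcfs
  gm <- build_genotype_matrix(paths, sim$design)
  gm_rev <- build_genotype_matrix(rev(paths), sim$design)
  expect_identical(gm, gm_rev)

  # line-by-line oracle: parse each body record by hand, apply thresholds
  plc <- pipeline_config()
  parsed <- list()
  for (p in paths) {
    lines <- readLines(p)
    s <- sub(".*\t", "", lines[grepl("^#CHROM", lines)])
    body <- lines[!startsWith(lines, "#")]
    f <- strsplit(body, "\t", fixed = TRUE)
    for (x in f) {
      gtf <- strsplit(x[10], ":", fixed = TRUE)[[1]]
      ad <- as.integer(strsplit(gtf[2], ",", fixed = TRUE)[[1]])
      gt <- c("0/0" = "hom_ref", "0/1" = "het", "1/1" = "hom_alt")[gtf[1]]
      qual <- as.numeric(x[6])
      dp <- as.integer(gtf[3])
      ok <- qual >= plc$min_base_quality && dp < plc$max_depth_exclusive &&
        (gt == "hom_ref" || ad[2] > plc$min_alt_reads_exclusive)
      parsed[[length(parsed) + 1]] <- tibble::tibble(
        chromosome = x[1], position = as.integer(x[2]), sample = s,
        state = if (ok) unname(gt) else "missing"
      )
    }
  }
  oracle <- dplyr::bind_rows(parsed)
  oracle_states <- oracle[oracle$state != "missing", ]

  long <- tidyr::pivot_longer(
    gm,
    cols = dplyr::all_of(attr(gm, "samples")),
    names_to = "sample", values_to = "state"
  )
  called <- long[long$state != "missing", ]
  joined <- dplyr::inner_join(
    called, oracle_states,
    by = c("chromosome", "position", "sample")
  )
  expect_equal(nrow(joined), nrow(called))
  expect_true(all(joined$state.x == joined$state.y))
  # per-state counts agree with the brute-force parse
  expect_equal(
    sort(table(called$state)), sort(table(oracle_states$state))
  )
})

test_that("conflicting reference alleles and excess alt alleles are handled", {
  dir <- withr::local_tempdir()
  design <- fixture_design(1)
  p1 <- file.path(dir, "high_1.vcf")
  p2 <- file.path(dir, "low_1.vcf")
  write_fixture_vcf(p1, "high_1", vcf_record("chr1", 500, "A", "G", 35, "1/1", "0,12", 12))
  write_fixture_vcf(p2, "low_1", vcf_record("chr1", 500, "C", "G", 35, "1/1", "0,12", 12))
  expect_error(
    build_genotype_matrix(c(p1, p2), design),
    class = "extremediff_error"
  )

  write_fixture_vcf(p1, "high_1", c(
    vcf_record("chr1", 500, "A", "G", 35, "1/1", "0,12", 12),
    vcf_record("chr1", 700, "A", "G", 35, "1/1", "0,12", 12)
  ))
  write_fixture_vcf(p2, "low_1", c(
    vcf_record("chr1", 500, "A", "C,T", 35, "1/2", "0,6,6", 12),
    vcf_record("chr1", 700, "A", "G", 35, "0/0", "12,0", 12)
  ))
  expect_warning(
    gm <- build_genotype_matrix(c(p1, p2), design),
    "alternate"
  )
  expect_equal(gm$position, 700L) # three-alt position dropped
  # sample missing in the design errors out
  expect_error(
    build_genotype_matrix(p1, fixture_design(2)),
    class = "extremediff_error"
  )
})
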