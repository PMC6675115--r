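small_cfg <- function(seed = 5) {
  sim_config(
    n_chromosomes = 2, chromosome_length_bp = 4e5, n_genes = 12,
    fraction_noncoding_genes = 0.25, n_background_snvs = 300,
    n_planted_differential = 12, n_planted_candidate_genes = 3,
    missing_rate = 0, filter_fail_rate = 0, seed = seed
  )
}

test_that("identical seeds give byte-identical study outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_cfg(), d1)
  simulate_study(small_cfg(), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      label = paste("md5 of", f)
    )
  }
  # a different seed changes the reference
  d3 <- withr::local_tempdir()
  simulate_study(small_cfg(seed = 6), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "reference.fa"))),
    unname(tools::md5sum(file.path(d3, "reference.fa")))
  ))
})

test_that("the configured non-coding fraction is honoured exactly", {
  ref <- simulate_reference(sim_config(
    n_chromosomes = 2, chromosome_length_bp = 4e5, n_genes = 10,
    fraction_noncoding_genes = 0.2, seed = 3
  ))
  expect_equal(sum(ref$genes$biotype == "ncRNA"), 2)
  expect_equal(nrow(ref$genes), 10)
  # genes are non-overlapping and separated by at least 12 kb
  by_chr <- split(ref$genes, ref$genes$chromosome)
  for (g in by_chr) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] - g$end[-nrow(g)] >= 12000))
    }
  }
  # a genome too small for the request errors out
  expect_error(
    simulate_reference(sim_config(
      n_chromosomes = 1, chromosome_length_bp = 5e4, n_genes = 40, seed = 1
    )),
    class = "extremediff_error"
  )
})

test_that("emitted coding transcripts re-parse into valid ORFs", {
  dir <- withr::local_tempdir()
  simulate_study(small_cfg(), dir)
  # independent re-parse: rtracklayer + Biostrings, own splicing code
  gr <- rtracklayer::import(file.path(dir, "genes.gff3"), format = "gff3")
  fa <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(fa) <- sub("\\s.*$", "", names(fa))
  meta <- S4Vectors::mcols(gr)
  cds <- gr[meta$type == "CDS"]
  parents <- vapply(
    S4Vectors::mcols(cds)$Parent, `[[`, character(1), 1
  )
  expect_gt(length(unique(parents)), 0)
  for (tx in unique(parents)) {
    iv <- cds[parents == tx]
    iv <- iv[order(GenomicRanges::start(iv))]
    chrom <- as.character(GenomicRanges::seqnames(iv))[1]
    strand <- as.character(GenomicRanges::strand(iv))[1]
    pieces <- vapply(seq_along(iv), function(r) {
      as.character(Biostrings::subseq(
        fa[[chrom]], GenomicRanges::start(iv)[r], GenomicRanges::end(iv)[r]
      ))
    }, character(1))
    spliced <- paste(pieces, collapse = "")
    dna <- Biostrings::DNAString(spliced)
    if (strand == "-") dna <- Biostrings::reverseComplement(dna)
    expect_equal(length(dna) %% 3, 0)
    prot <- as.character(Biostrings::translate(dna))
    expect_equal(substr(as.character(dna), 1, 3), "ATG")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    # no premature stop codon
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("a noiseless cohort is fully called and its scan recovers the planted set", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_cfg(), dir)
  expect_equal(nrow(sim$truth_sites), 12)
  expect_equal(nrow(sim$truth_genes), 3)

  # hand-parse every VCF body: collect genotype per (site, sample)
  recs <- list()
  for (p in sim$paths$vcfs) {
    lines <- readLines(p)
    s <- sub(".*\t", "", lines[grepl("^#CHROM", lines)])
    body <- lines[!startsWith(lines, "#")]
    f <- strsplit(body, "\t", fixed = TRUE)
    recs[[length(recs) + 1]] <- tibble::tibble(
      chromosome = vapply(f, `[`, character(1), 1),
      position = as.integer(vapply(f, `[`, character(1), 2)),
      ref = vapply(f, `[`, character(1), 4),
      alt = vapply(f, `[`, character(1), 5),
      sample = s,
      gt = sub(":.*", "", vapply(f, `[`, character(1), 10))
    )
  }
  long <- dplyr::bind_rows(recs)
  # noiseless: every planted site is called in all eight samples
  planted_keys <- paste(sim$truth_sites$chromosome, sim$truth_sites$position)
  per_site <- table(paste(long$chromosome, long$position))
  expect_true(all(per_site[planted_keys] == 8))

  # exhaustive opposite-fixed scan
  highs <- sim$design$high_sample
  lows <- sim$design$low_sample
  wide <- tidyr::pivot_wider(
    long,
    id_cols = c("chromosome", "position", "ref", "alt"),
    names_from = "sample", values_from = "gt"
  )
  hom <- function(x) !is.na(x) & x %in% c("0/0", "1/1")
  found <- character(0)
  for (i in seq_len(nrow(wide))) {
    h <- unlist(wide[i, highs])
    l <- unlist(wide[i, lows])
    if (all(hom(h)) && all(hom(l)) &&
      length(unique(h)) == 1 && length(unique(l)) == 1 && h[1] != l[1]) {
      found <- c(found, paste(wide$chromosome[i], wide$position[i]))
    }
  }
  expect_setequal(found, planted_keys)
})

test_that("planted candidate genes sit within 1 cM of a QTL peak; decoys never do", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_cfg(), dir)
  map <- readr::read_csv(
    file.path(dir, "genetic_map.csv"),
    show_col_types = FALSE
  )
  qtl <- readr::read_csv(
    file.path(dir, "qtl_table.csv"),
    show_col_types = FALSE
  )
  # anchors re-read from file are strictly increasing in both axes
  for (ch in unique(map$chromosome)) {
    m <- map[map$chromosome == ch, ]
    expect_true(all(diff(m$bp) > 0))
    expect_true(all(diff(m$cM) > 0))
  }
  # direct two-point interpolation, written out by hand
  cm_of <- function(ch, bp) {
    m <- map[map$chromosome == ch, ]
    i <- max(1, min(findInterval(bp, m$bp), nrow(m) - 1))
    m$cM[i] + (bp - m$bp[i]) * (m$cM[i + 1] - m$cM[i]) / (m$bp[i + 1] - m$bp[i])
  }
  peaks_of <- function(rows) {
    unlist(lapply(strsplit(rows$peaks_cM, ";"), as.numeric))
  }
  for (g in sim$truth_genes$gene_id) {
    info <- sim$genes[sim$genes$gene_id == g, ]
    gcm <- cm_of(info$chromosome, info$start)
    qs <- qtl[qtl$chromosome == info$chromosome, ]
    expect_lt(min(abs(gcm - peaks_of(qs))), 1.0)
  }
  # decoy QTLs are at least 3 cM from every gene on their chromosome
  decoys <- qtl[qtl$source == "SimDecoy", ]
  for (i in seq_len(nrow(decoys))) {
    on_chr <- sim$genes[sim$genes$chromosome == decoys$chromosome[i], ]
    if (nrow(on_chr) == 0) next
    gcms <- vapply(
      on_chr$start, function(b) cm_of(decoys$chromosome[i], b), numeric(1)
    )
    for (pk in peaks_of(decoys[i, ])) {
      expect_gte(min(abs(gcms - pk)), 3.0)
    }
  }
  # the planted enriched set contains exactly the candidate genes
  gmt <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_setequal(gmt$genes[[1]], sim$truth_genes$gene_id)
})

test_that("planted sites land in their intended annotation category", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_cfg(seed = 11), dir)
  ann <- assign_category(
    sim$truth_sites, sim$genes, sim$features,
    read_reference(file.path(dir, "reference.fa"))
  )
  expect_equal(ann$category, sim$truth_sites$intended_category)
  expect_false(any(ann$ref_mismatch))
})

test_that("configuration invariants are validated", {
  expect_error(sim_config(het_rate = 1.2), class = "extremediff_error")
  expect_error(sim_config(n_genes = 0), class = "extremediff_error")
  expect_error(
    sim_config(n_planted_candidate_genes = 10, n_planted_differential = 5),
    class = "extremediff_error"
  )
  expect_error(
    sim_config(n_planted_candidate_genes = 99, n_genes = 50),
    class = "extremediff_error"
  )
})
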