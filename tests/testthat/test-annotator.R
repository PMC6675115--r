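fix <- fixture_gene_set()

ref_base_at <- function(reference, chrom, pos) {
  substr(as.character(reference[[chrom]]), pos, pos)
}

test_that("near-gene worked examples: strand-aware upstream/downstream distances", {
  # gene starting at 14,558,546 on +: SNV at 14,558,465 is upstream, 81 bp
  g <- fixture_gene("gU", "chrU", 14558546L, "+", c(855L, 2000L), 1000L, 30, 60)
  ref <- Biostrings::DNAStringSet(c(chrU = paste(
    rep("A", 14600000), collapse = ""
  )))
  snv <- tibble::tibble(
    chromosome = "chrU", position = 14558465L, ref = "A", alt = "G"
  )
  ann <- assign_category(snv, g$genes, g$features, ref)
  expect_equal(ann$category, "upstream")
  expect_equal(ann$distance_bp, 81)
  expect_equal(ann$gene_id, "gU")

  # gene starting at 44,657,521 on -: SNV at 44,656,702 is downstream, 819 bp
  g2 <- fixture_gene("gD", "chrD", 44657521L, "-", c(900L, 1500L), 1200L, 40, 50)
  ref2 <- Biostrings::DNAStringSet(c(chrD = paste(
    rep("A", 44700000), collapse = ""
  )))
  snv2 <- tibble::tibble(
    chromosome = "chrD", position = 44656702L, ref = "A", alt = "G"
  )
  ann2 <- assign_category(snv2, g2$genes, g2$features, ref2)
  expect_equal(ann2$category, "downstream")
  expect_equal(ann2$distance_bp, 819)
})

test_that("category assignment matches the brute-force oracle on random sites", {
  set.seed(51)
  n <- 1000
  sites <- tibble::tibble(
    chromosome = sample(c("chrA", "chrB"), n, replace = TRUE),
    position = sample(1:200000, n, replace = TRUE)
  )
  # targeted boundary and overlap cases (g01 starts at 5000 on +)
  sites <- dplyr::bind_rows(sites, tibble::tibble(
    chromosome = c("chrA", "chrA", "chrA", "chrB", "chrB", "chrB", "chrB"),
    position = c(4000L, 3999L, 5000L, 151200L, 152000L, 171000L, 171799L)
  ))
  sites$ref <- vapply(seq_len(nrow(sites)), function(i) {
    ref_base_at(fix$reference, sites$chromosome[i], sites$position[i])
  }, character(1))
  sites$alt <- ifelse(sites$ref == "A", "G", "A")

  ann <- assign_category(sites, fix$genes, fix$features, fix$reference)
  for (i in seq_len(nrow(sites))) {
    want <- oracle_category(
      sites$chromosome[i], sites$position[i], fix$genes, fix$features
    )
    expect_equal(ann$category[i], want$category)
    if (!is.na(want$gene)) expect_equal(ann$gene_id[i], want$gene)
    expect_equal(ann$distance_bp[i], want$dist)
  }
  # every site gets exactly one category from the fixed vocabulary
  expect_true(all(ann$category %in% c(
    "exonic", "UTR5", "UTR3", "intronic", "ncRNA_exonic", "ncRNA_intronic",
    "upstream", "downstream", "upstream;downstream", "intergenic"
  )))
  # a site is intergenic iff farther than 1 kb from every gene
  inter <- ann$category == "intergenic"
  expect_true(all(ann$distance_bp[inter] > 1000))
  expect_true(all(ann$distance_bp[!inter & ann$distance_bp > 0] <= 1000))
  # unknown chromosome is a data error
  expect_error(
    assign_category(
      tibble::tibble(chromosome = "chrZ", position = 1L, ref = "A", alt = "C"),
      fix$genes, fix$features, fix$reference
    ),
    class = "extremediff_error"
  )
})

test_that("a reference mismatch is flagged, never dropped", {
  pos <- 30000L
  truth <- ref_base_at(fix$reference, "chrA", pos)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  snv <- tibble::tibble(
    chromosome = "chrA", position = pos, ref = wrong,
    alt = setdiff(c("A", "C", "G", "T"), c(truth, wrong))[1]
  )
  ann <- assign_category(snv, fix$genes, fix$features, fix$reference)
  expect_equal(nrow(ann), 1)
  expect_true(ann$ref_mismatch)
})

# a hand-built mini locus with fully controlled CDS content:
# CDS = ATG TAC GGA TAA at 101..112 (+) and its reverse complement
# at 201..212 (-), plus a spliced copy split 301..306 / 351..356
mini_locus <- function() {
  chars <- rep("A", 400)
  plus <- strsplit("ATGTACGGATAA", "")[[1]]
  chars[101:112] <- plus
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars[201:212] <- rev(unname(comp[plus]))
  chars[301:306] <- plus[1:6]
  chars[351:356] <- plus[7:12]
  ref <- Biostrings::DNAStringSet(c(chrM = paste(chars, collapse = "")))
  cds_plus <- tibble::tibble(start = 101L, end = 112L)
  cds_minus <- tibble::tibble(start = 201L, end = 212L)
  cds_spliced <- tibble::tibble(start = c(301L, 351L), end = c(306L, 356L))
  list(
    ref = ref, plus = cds_plus, minus = cds_minus, spliced = cds_spliced
  )
}

test_that("coding effects equal translation-table lookup for all 9 substitutions", {
  loc <- mini_locus()
  # codon 2 (TAC) occupies 104..106 on the plus strand
  codon_start <- 104L
  ref_codon <- "TAC"
  for (off in 0:2) {
    pos <- codon_start + off
    ref <- substr(ref_codon, off + 1, off + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- coding_effect(pos, ref, alt, loc$plus, "+", loc$ref, "chrM")
      mut <- ref_codon
      substr(mut, off + 1, off + 1) <- alt
      aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
      aa_alt <- Biostrings::GENETIC_CODE[[mut]]
      want <- if (aa_ref == aa_alt) {
        "synonymous"
      } else if (aa_alt == "*") {
        "stopgain"
      } else if (aa_ref == "*") {
        "stoploss"
      } else {
        "nonsynonymous"
      }
      expect_equal(got, want)
    }
  }
  # TAC -> TAA via the third position is a stop gain
  expect_equal(
    coding_effect(106L, "C", "A", loc$plus, "+", loc$ref, "chrM"), "stopgain"
  )
  # degenerate third position GGA -> GGC is synonymous
  expect_equal(
    coding_effect(109L, "A", "C", loc$plus, "+", loc$ref, "chrM"), "synonymous"
  )
  # losing the terminal stop TAA -> TCA
  expect_equal(
    coding_effect(111L, "A", "C", loc$plus, "+", loc$ref, "chrM"), "stoploss"
  )
})

test_that("coding effects respect strand and splicing", {
  loc <- mini_locus()
  # minus strand: transcript position 9 (third base of GGA) sits at
  # genomic 204; transcript A is genomic T; transcript C would be genomic G
  expect_equal(
    coding_effect(204L, "T", "G", loc$minus, "-", loc$ref, "chrM"),
    "synonymous"
  )
  # minus strand stop gain: transcript position 6 (TAC -> TAA) at 207
  expect_equal(
    coding_effect(207L, "G", "T", loc$minus, "-", loc$ref, "chrM"),
    "stopgain"
  )
  # spliced CDS: GGA's third base is transcript position 9 = genomic 353
  expect_equal(
    coding_effect(353L, "A", "C", loc$spliced, "+", loc$ref, "chrM"),
    "synonymous"
  )
  # CDS length not divisible by three -> unknown
  bad_cds <- tibble::tibble(start = 101L, end = 111L)
  expect_equal(
    coding_effect(105L, "A", "G", bad_cds, "+", loc$ref, "chrM"), "unknown"
  )
  # reference inconsistency -> unknown
  expect_equal(
    coding_effect(104L, "G", "C", loc$plus, "+", loc$ref, "chrM"), "unknown"
  )
  # outside the CDS is a contract violation
  expect_error(
    coding_effect(150L, "A", "G", loc$plus, "+", loc$ref, "chrM"),
    class = "extremediff_error"
  )
})

test_that("gene attachment honours the 5 kb window inclusively", {
  genes <- fix$genes
  g01 <- genes[genes$gene_id == "g01", ] # chrA 5000..? on +
  diffs <- tibble::tibble(
    chromosome = "chrA",
    position = c(g01$start - 4999L, g01$start - 5000L, g01$start - 5001L),
    ref = "A", alt = "G"
  )
  att <- attach_to_genes(diffs, genes)
  expect_true((g01$start - 4999L) %in% att$position)
  expect_true((g01$start - 5000L) %in% att$position)
  expect_false((g01$start - 5001L) %in% att$position)

  # retained count equals a brute-force all-pairs distance computation
  set.seed(52)
  rnd <- tibble::tibble(
    chromosome = sample(c("chrA", "chrB"), 100, replace = TRUE),
    position = sample(1:200000, 100),
    ref = "A", alt = "G"
  )
  att2 <- attach_to_genes(rnd, genes)
  coding <- genes[genes$biotype == "coding", ]
  want <- 0L
  for (i in seq_len(nrow(rnd))) {
    near <- FALSE
    for (j in seq_len(nrow(coding))) {
      if (rnd$chromosome[i] != coding$chromosome[j]) next
      d <- if (rnd$position[i] >= coding$start[j] &&
        rnd$position[i] <= coding$end[j]) {
        0
      } else {
        min(
          abs(rnd$position[i] - coding$start[j]),
          abs(rnd$position[i] - coding$end[j])
        )
      }
      if (d <= 5000) near <- TRUE
    }
    if (near) want <- want + 1L
  }
  expect_equal(attr(att2, "n_retained"), want)
})

test_that("category summaries report half-up percentages of the annotated total", {
  ann <- tibble::tibble(
    chromosome = "chr1", position = 1:8, ref = "A", alt = "G",
    category = c(
      "intergenic", "intergenic", "intergenic", "intronic", "exonic",
      "exonic", "UTR5", "upstream"
    ),
    exonic_effect = c(
      rep("not_applicable", 4), "synonymous", "nonsynonymous",
      "not_applicable", "not_applicable"
    ),
    gene_id = NA_character_, distance_bp = 0, ref_mismatch = FALSE
  )
  s <- summarize_categories(ann)
  expect_equal(attr(s, "total_annotated"), 8)
  main <- s[is.na(s$effect), ]
  expect_equal(sum(main$count), 8)
  expect_equal(
    main$percentage[main$category == "intergenic"],
    round_half_up(100 * 3 / 8, 2)
  )
  # exonic effect subcounts sum to the exonic total
  expect_equal(
    sum(s$count[!is.na(s$effect)]), main$count[main$category == "exonic"]
  )
  # a single category captures 100.00%
  one <- summarize_categories(ann[1:3, ])
  expect_equal(one$percentage[one$category == "intergenic"], 100)
  expect_error(summarize_categories(ann[0, ]), class = "extremediff_error")
})
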