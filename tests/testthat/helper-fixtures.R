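# Fixture builders and independent brute-force oracles. Everything here is
# deliberately written with plain loops, separate from the package's
# vectorized/GRanges implementations, so it can serve as an oracle.

# Build one gene with explicit exon/intron lengths; returns genes/features
# rows in the package's tabular gene-model representation.
fixture_gene <- function(gene_id, chrom, start, strand, ex_len, in_len,
                         u5 = 0, u3 = 0, biotype = "coding") {
  tx_id <- paste0("t_", gene_id)
  ex_start <- integer(length(ex_len))
  pos <- start
  feats <- list()
  for (i in seq_along(ex_len)) {
    ex_start[i] <- pos
    pos <- pos + ex_len[i] + if (i < length(ex_len)) in_len[i] else 0L
  }
  ex_end <- ex_start + ex_len - 1L
  end <- ex_end[length(ex_end)]
  feats[[1]] <- tibble::tibble(
    gene_id = gene_id, transcript_id = tx_id, type = "exon",
    start = ex_start, end = ex_end
  )
  if (biotype == "coding") {
    total <- sum(ex_len)
    cds_len <- total - u5 - u3
    stopifnot(cds_len > 0)
    # walk exons in transcription order, slicing UTR5 / CDS / UTR3
    ex_order <- if (strand == "+") seq_along(ex_len) else rev(seq_along(ex_len))
    regions <- list(
      c("five_prime_UTR", 1, u5),
      c("CDS", u5 + 1, u5 + cds_len),
      c("three_prime_UTR", u5 + cds_len + 1, total)
    )
    tpos <- 1L
    rows <- list()
    for (e in ex_order) {
      a <- tpos
      b <- tpos + ex_len[e] - 1L
      for (r in regions) {
        o1 <- max(a, as.integer(r[2]))
        o2 <- min(b, as.integer(r[3]))
        if (o1 > o2) next
        if (strand == "+") {
          gs <- ex_start[e] + (o1 - a)
          ge <- ex_start[e] + (o2 - a)
        } else {
          ge <- ex_end[e] - (o1 - a)
          gs <- ex_end[e] - (o2 - a)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = gene_id, transcript_id = tx_id, type = r[1],
          start = gs, end = ge
        )
      }
      tpos <- b + 1L
    }
    feats[[2]] <- dplyr::bind_rows(rows)
  }
  list(
    genes = tibble::tibble(
      gene_id = gene_id, chromosome = chrom, strand = strand,
      start = start, end = end, biotype = biotype
    ),
    features = dplyr::bind_rows(feats)
  )
}

# A 20-gene fixture on two chromosomes: mixed strands, an ncRNA pair, and
# two deliberately overlapping genes (g_ov1/g_ov2) to exercise precedence.
fixture_gene_set <- function() {
  specs <- list(
    list("g01", "chrA", 5000L, "+", c(200L, 300L), 1000L, 30, 45),
    list("g02", "chrA", 20000L, "-", c(150L, 150L, 300L), c(900L, 1200L), 20, 40),
    list("g03", "chrA", 40000L, "+", c(400L, 200L), 1500L, 50, 60),
    list("g04", "chrA", 60000L, "-", c(250L, 250L), 2000L, 25, 30),
    list("g05", "chrA", 80000L, "+", c(600L), integer(0), 60, 90),
    list("g06", "chrA", 100000L, "-", c(300L, 300L), 1100L, 35, 55),
    list("g07", "chrA", 120000L, "+", c(200L, 200L, 200L), c(800L, 800L), 40, 50),
    list("g08", "chrA", 140000L, "-", c(500L), integer(0), 45, 35),
    list("g11", "chrB", 6000L, "+", c(350L, 250L), 1300L, 30, 60),
    list("g12", "chrB", 25000L, "-", c(220L, 380L), 900L, 55, 45),
    list("g13", "chrB", 45000L, "+", c(450L), integer(0), 40, 50),
    list("g14", "chrB", 65000L, "-", c(180L, 420L), 1600L, 20, 40),
    list("g15", "chrB", 85000L, "+", c(320L, 280L), 1000L, 65, 45),
    list("g16", "chrB", 105000L, "-", c(240L, 360L), 1200L, 30, 30)
  )
  parts <- lapply(specs, function(s) {
    fixture_gene(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]], s[[7]], s[[8]])
  })
  # ncRNA genes
  parts <- c(parts, list(
    fixture_gene("g09", "chrA", 160000L, "+", c(300L, 200L), 700L,
      biotype = "ncRNA"
    ),
    fixture_gene("g10", "chrA", 175000L, "-", c(400L), integer(0),
      biotype = "ncRNA"
    ),
    fixture_gene("g17", "chrB", 125000L, "+", c(500L), integer(0),
      biotype = "ncRNA"
    )
  ))
  # overlapping pair: g_ov2 starts inside g_ov1's intron
  parts <- c(parts, list(
    fixture_gene("g_ov1", "chrB", 150000L, "+", c(200L, 200L), 4000L, 30, 40),
    fixture_gene("g_ov2", "chrB", 151000L, "-", c(300L, 300L), 600L, 25, 35),
    # close pair 1.5 kb apart so a site can sit between two flanks
    fixture_gene("g_nb1", "chrB", 170000L, "+", c(300L), integer(0), 30, 40),
    fixture_gene("g_nb2", "chrB", 171800L, "+", c(300L), integer(0), 30, 40)
  ))
  genes <- dplyr::bind_rows(lapply(parts, `[[`, "genes"))
  features <- dplyr::bind_rows(lapply(parts, `[[`, "features"))
  reference <- withr::with_seed(99, Biostrings::DNAStringSet(c(
    chrA = paste(sample(c("A", "C", "G", "T"), 200000, replace = TRUE),
      collapse = ""
    ),
    chrB = paste(sample(c("A", "C", "G", "T"), 200000, replace = TRUE),
      collapse = ""
    )
  )))
  list(genes = genes, features = features, reference = reference)
}

# Brute-force category oracle: tests every site against every feature
# interval with plain loops and the documented precedence.
oracle_category <- function(chrom, pos, genes, features, near = 1000) {
  prio <- c(
    exonic = 1, UTR5 = 2, UTR3 = 3, intronic = 4,
    ncRNA_exonic = 5, ncRNA_intronic = 6
  )
  in_any <- function(fe, p) {
    any(p >= fe$start & p <= fe$end)
  }
  genic <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chromosome != chrom || pos < g$start || pos > g$end) next
    fe <- features[features$gene_id == g$gene_id, ]
    cat <- if (g$biotype == "coding") {
      if (in_any(fe[fe$type == "CDS", ], pos)) {
        "exonic"
      } else if (in_any(fe[fe$type == "five_prime_UTR", ], pos)) {
        "UTR5"
      } else if (in_any(fe[fe$type == "three_prime_UTR", ], pos)) {
        "UTR3"
      } else {
        "intronic"
      }
    } else {
      if (in_any(fe[fe$type == "exon", ], pos)) "ncRNA_exonic" else "ncRNA_intronic"
    }
    genic[[length(genic) + 1]] <- list(cat = cat, gene = g$gene_id)
  }
  if (length(genic) > 0) {
    ord <- order(
      vapply(genic, function(x) prio[[x$cat]], numeric(1)),
      vapply(genic, function(x) x$gene, character(1))
    )
    return(list(
      category = genic[[ord[1]]]$cat, gene = genic[[ord[1]]]$gene, dist = 0
    ))
  }
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chromosome != chrom) next
    d <- min(abs(pos - g$start), abs(pos - g$end))
    before <- pos >= g$start - near && pos <= g$start - 1
    after <- pos >= g$end + 1 && pos <= g$end + near
    side <- NULL
    if (before) side <- if (g$strand == "+") "upstream" else "downstream"
    if (after) side <- if (g$strand == "+") "downstream" else "upstream"
    if (!is.null(side)) {
      hits[[length(hits) + 1]] <- list(side = side, gene = g$gene_id, dist = d)
    }
  }
  if (length(hits) > 0) {
    sides <- vapply(hits, function(x) x$side, character(1))
    gene_ids <- vapply(hits, function(x) x$gene, character(1))
    dists <- vapply(hits, function(x) x$dist, numeric(1))
    ord <- order(dists, gene_ids)
    both <- length(unique(sides)) == 2 && length(unique(gene_ids)) >= 2
    return(list(
      category = if (both) "upstream;downstream" else sides[ord[1]],
      gene = gene_ids[ord[1]], dist = min(dists)
    ))
  }
  on_chr <- genes[genes$chromosome == chrom, ]
  d <- if (nrow(on_chr) == 0) {
    NA_real_
  } else {
    min(pmin(abs(pos - on_chr$start), abs(pos - on_chr$end)))
  }
  list(category = "intergenic", gene = NA_character_, dist = d)
}

# Build a genotype matrix tibble directly from a state matrix.
fixture_matrix <- function(states, samples,
                           chrom = "chr1", ref = "A", alt = "G") {
  n <- nrow(states)
  gm <- tibble::tibble(
    chromosome = chrom, position = seq_len(n) * 100L, ref = ref, alt = alt
  )
  for (j in seq_along(samples)) gm[[samples[j]]] <- states[, j]
  attr(gm, "samples") <- samples
  gm
}

fixture_design <- function(n_fam = 4) {
  tibble::tibble(
    family_id = paste0("fam", seq_len(n_fam)),
    high_sample = paste0("high_", seq_len(n_fam)),
    low_sample = paste0("low_", seq_len(n_fam))
  )
}

# Independent hypergeometric upper tail by direct binomial-coefficient
# enumeration.
oracle_hyper_tail <- function(k, n, K, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Write a minimal single-sample VCF by hand (independent of the package's
# writer).
write_fixture_vcf <- function(path, sample, records,
                              contigs = c(chr1 = 100000L)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample
    ), collapse = "\t")
  )
  writeLines(c(header, records), path)
}

vcf_record <- function(chrom, pos, ref, alt, qual, gt, ad, dp) {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT:AD:DP",
    sprintf("%s:%s:%d", gt, ad, dp),
    sep = "\t"
  )
}
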