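#' Simulate a reference genome with gene models
#'
#' Generates random chromosome sequences and places non-overlapping gene
#' models on them, separated by at least 12 kb so that the 1 kb
#' (up/downstream) and 5 kb (gene attachment) distance classes are always
#' unambiguous. Coding genes carry a single transcript with 5' UTR, CDS and
#' 3' UTR split across 2-4 exons; the reference sequence is rewritten under
#' each CDS so that the spliced coding sequence begins with ATG, ends with a
#' stop codon, contains no internal stop, and has length divisible by 3.
#' Non-coding (ncRNA) genes carry exons only; their count is exactly
#' `round(fraction_noncoding_genes * n_genes)`.
#'
#' All draws derive from `config$seed`; repeated calls with the same
#' configuration are identical.
#'
#' @param config A [sim_config()].
#' @return A list with elements `reference` (a named
#'   [Biostrings::DNAStringSet]), `genes` (tibble: gene_id, chromosome,
#'   strand, start, end, biotype) and `features` (tibble: gene_id,
#'   transcript_id, type, start, end; types exon/CDS/five_prime_UTR/
#'   three_prime_UTR, 1-based inclusive).
#' @examples
#' ref <- simulate_reference(sim_config(n_genes = 6, seed = 1))
#' ref$genes
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(config) {
  n_chrom <- config$n_chromosomes
  chrom_len <- config$chromosome_length_bp
  chroms <- paste0("chr", seq_len(n_chrom))
  seqs <- lapply(chroms, function(x) {
    sample(DNA_BASES, chrom_len, replace = TRUE)
  })
  names(seqs) <- chroms

  n_nc <- round(config$fraction_noncoding_genes * config$n_genes)
  nc_idx <- if (n_nc > 0) sample(config$n_genes, n_nc) else integer(0)

  genes <- list()
  features <- list()
  # one placement cursor per chromosome; genes are dealt round-robin
  cursors <- vapply(
    seq_len(n_chrom), function(i) 3000L + sample(0:2000, 1), integer(1)
  )
  for (i in seq_len(config$n_genes)) {
    gene_id <- sprintf("g%03d", i)
    tx_id <- sprintf("t%03d", i)
    coding <- !(i %in% nc_idx)
    strand <- sample(c("+", "-"), 1)
    if (coding) {
      n_ex <- sample(2:4, 1)
      ex_len <- sample(120:300, n_ex, replace = TRUE)
      u5 <- sample(20:60, 1)
      u3 <- sample(20:60, 1)
      total_ex <- sum(ex_len)
      u3 <- u3 + (total_ex - u5 - u3) %% 3L
      cds_len <- total_ex - u5 - u3
    } else {
      n_ex <- sample(1:3, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      u5 <- u3 <- cds_len <- 0L
    }
    in_len <- if (n_ex > 1) sample(800:2000, n_ex - 1, replace = TRUE) else integer(0)
    span <- sum(ex_len) + sum(in_len)

    tried <- ((i - 1L) %% n_chrom) + c(seq_len(n_chrom)) # preferred first
    tried <- ((tried - 1L) %% n_chrom) + 1L
    chrom_i <- NA_integer_
    for (ci in tried) {
      if (cursors[ci] + span - 1L <= chrom_len - 2000L) {
        chrom_i <- ci
        break
      }
    }
    if (is.na(chrom_i)) {
      stop_bad_arg(paste0(
        "chromosomes too short to host ", config$n_genes,
        " genes with 12 kb spacing; increase `chromosome_length_bp` ",
        "or `n_chromosomes`"
      ))
    }
    start <- cursors[chrom_i]
    end <- start + span - 1L
    chrom <- chroms[chrom_i]
    cursors[chrom_i] <- end + 12000L + sample(0:3000, 1)

    ex_start <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
    ex_end <- ex_start + ex_len - 1L
    exons <- tibble(start = ex_start, end = ex_end)

    feats <- tibble(
      gene_id = gene_id, transcript_id = tx_id, type = "exon",
      start = exons$start, end = exons$end
    )
    if (coding) {
      pieces <- split_transcript_regions(exons, strand, u5, cds_len, u3)
      feats <- bind_rows(
        feats,
        tibble(
          gene_id = gene_id, transcript_id = tx_id,
          type = pieces$type, start = pieces$start, end = pieces$end
        )
      )
      seqs[[chrom]] <- inject_cds(seqs[[chrom]], pieces, strand, cds_len)
    }
    genes[[i]] <- tibble(
      gene_id = gene_id, chromosome = chrom, strand = strand,
      start = start, end = end,
      biotype = if (coding) "coding" else "ncRNA"
    )
    features[[i]] <- feats
  }

  reference <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = "")
  )
  names(reference) <- chroms
  list(
    reference = reference,
    genes = bind_rows(genes),
    features = bind_rows(features),
    config = config
  )
}

# Split a transcript's exons (genomic coordinates) into UTR5/CDS/UTR3 pieces.
# Returns pieces in TRANSCRIPTION order with genomic start/end columns.
split_transcript_regions <- function(exons, strand, u5, cds_len, u3) {
  total <- sum(exons$end - exons$start + 1L)
  regions <- tibble(
    type = c("five_prime_UTR", "CDS", "three_prime_UTR"),
    from = c(1L, u5 + 1L, u5 + cds_len + 1L),
    to = c(u5, u5 + cds_len, total)
  ) %>% filter(.data$to >= .data$from)

  ex_order <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  out <- list()
  tpos <- 1L
  for (e in ex_order) {
    gs <- exons$start[e]
    ge <- exons$end[e]
    len <- ge - gs + 1L
    a <- tpos
    b <- tpos + len - 1L
    for (r in seq_len(nrow(regions))) {
      o1 <- max(a, regions$from[r])
      o2 <- min(b, regions$to[r])
      if (o1 > o2) next
      if (strand == "+") {
        out[[length(out) + 1L]] <- tibble(
          type = regions$type[r],
          start = gs + (o1 - a), end = gs + (o2 - a),
          tx_from = o1, tx_to = o2
        )
      } else {
        out[[length(out) + 1L]] <- tibble(
          type = regions$type[r],
          start = ge - (o2 - a), end = ge - (o1 - a),
          tx_from = o1, tx_to = o2
        )
      }
    }
    tpos <- b + 1L
  }
  bind_rows(out)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# overwrite chromosome bases under the CDS with a valid coding sequence
inject_cds <- function(seq_chars, pieces, strand, cds_len) {
  n_codons <- cds_len %/% 3L
  all_codons <- apply(
    expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE),
    1L, paste, collapse = ""
  )
  sense <- setdiff(all_codons, STOP_CODONS)
  sense <- setdiff(sense, "ATG") # keep internal ATGs out for tidy re-parsing
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  cds_seq <- paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
  bases <- strsplit(cds_seq, "")[[1]]

  cds_pieces <- pieces %>% filter(.data$type == "CDS") %>% arrange(.data$tx_from)
  gpos <- unlist(lapply(seq_len(nrow(cds_pieces)), function(r) {
    if (strand == "+") {
      seq(cds_pieces$start[r], cds_pieces$end[r])
    } else {
      seq(cds_pieces$end[r], cds_pieces$start[r])
    }
  }))
  stopifnot(length(gpos) == cds_len)
  if (strand == "-") bases <- unname(COMPLEMENT[bases])
  seq_chars[gpos] <- bases
  seq_chars
}
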