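#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  # drop description after first whitespace so names match GFF3 seqids
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Write a reference genome to FASTA
#'
#' @param reference Named [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 70L)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits gene / mRNA (or ncRNA) / exon / CDS / five_prime_UTR /
#' three_prime_UTR features with 1-based inclusive coordinates and computed
#' CDS phase. Output is deterministic for a fixed input.
#'
#' @param genes Gene tibble (`gene_id`, `chromosome`, `strand`, `start`,
#'   `end`, `biotype`).
#' @param features Feature tibble (`gene_id`, `transcript_id`, `type`,
#'   `start`, `end`).
#' @param path Output file.
#' @param seq_lengths Optional named vector of chromosome lengths for
#'   `##sequence-region` directives.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, features, path, seq_lengths = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(seq_lengths)) {
    lines <- c(lines, sprintf(
      "##sequence-region %s 1 %d", names(seq_lengths), as.integer(seq_lengths)
    ))
  }
  genes <- genes %>% arrange(chrom_rank(.data$chromosome), .data$start)
  gff_row <- function(seqid, source, type, start, end, strand, phase, attrs) {
    paste(seqid, source, type, start, end, ".", strand, phase, attrs,
      sep = "\t"
    )
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    feats <- features %>%
      filter(.data$gene_id == g$gene_id) %>%
      arrange(.data$transcript_id, .data$start, .data$type)
    lines <- c(lines, gff_row(
      g$chromosome, "extremediff", "gene", g$start, g$end, g$strand, ".",
      sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype)
    ))
    for (tx in unique(feats$transcript_id)) {
      tx_feats <- feats %>% filter(.data$transcript_id == tx)
      tx_type <- if (g$biotype == "coding") "mRNA" else "ncRNA"
      lines <- c(lines, gff_row(
        g$chromosome, "extremediff", tx_type,
        min(tx_feats$start), max(tx_feats$end), g$strand, ".",
        sprintf("ID=%s;Parent=%s", tx, g$gene_id)
      ))
      cds <- tx_feats %>% filter(.data$type == "CDS")
      phases <- rep(".", nrow(tx_feats))
      if (nrow(cds) > 0) {
        ord <- if (g$strand == "+") order(cds$start) else order(-cds$start)
        lens <- (cds$end - cds$start + 1L)[ord]
        cum_before <- cumsum(c(0L, head(lens, -1)))
        ph <- (3L - cum_before %% 3L) %% 3L
        cds_phase <- integer(nrow(cds))
        cds_phase[ord] <- ph
        phases[tx_feats$type == "CDS"] <- as.character(cds_phase)
      }
      lines <- c(lines, vapply(seq_len(nrow(tx_feats)), function(r) {
        gff_row(
          g$chromosome, "extremediff", tx_feats$type[r],
          tx_feats$start[r], tx_feats$end[r], g$strand, phases[r],
          sprintf("ID=%s.%s%d;Parent=%s", tx, tolower(tx_feats$type[r]), r, tx)
        )
      }, character(1)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) into the tabular gene-model
#' representation used throughout the package. Gene biotype is taken from a
#' `biotype` attribute when present, otherwise inferred from the presence of
#' CDS features.
#'
#' @param path GFF3 file.
#' @return A list with tibbles `genes` and `features` (see
#'   [simulate_reference()] for the schemas).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  tb <- tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(meta$type),
    id = if ("ID" %in% names(meta)) as.character(meta$ID) else NA_character_,
    parent = if ("Parent" %in% names(meta)) {
      vapply(meta$Parent, function(p) {
        if (length(p) == 0) NA_character_ else as.character(p[[1]])
      }, character(1))
    } else {
      NA_character_
    },
    biotype = if ("biotype" %in% names(meta)) {
      as.character(meta$biotype)
    } else {
      NA_character_
    }
  )
  genes <- tb %>%
    filter(.data$type == "gene") %>%
    select(
      gene_id = "id", "chromosome", "strand", "start", "end", "biotype"
    )
  tx <- tb %>%
    filter(.data$type %in% c("mRNA", "ncRNA", "transcript")) %>%
    select(transcript_id = "id", gene_id = "parent")
  features <- tb %>%
    filter(.data$type %in% c(
      "exon", "CDS", "five_prime_UTR", "three_prime_UTR"
    )) %>%
    select(transcript_id = "parent", "type", "start", "end") %>%
    left_join(tx, by = "transcript_id") %>%
    select("gene_id", "transcript_id", "type", "start", "end")
  if (anyNA(genes$biotype)) {
    coding_genes <- unique(features$gene_id[features$type == "CDS"])
    genes <- genes %>%
      mutate(biotype = ifelse(
        is.na(.data$biotype),
        ifelse(.data$gene_id %in% coding_genes, "coding", "ncRNA"),
        .data$biotype
      ))
  }
  list(genes = genes, features = features)
}

#' Read and write gene-set collections (GMT)
#'
#' One set per line: set id, description/label, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file.
#' @param gene_sets Tibble with columns `set_id`, `label` and list-column
#'   `genes`.
#' @return `read_gmt()`: a tibble with columns `set_id`, `label`,
#'   `collection` and list-column `genes`. `write_gmt()`: `path`, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    set_id = vapply(parts, `[`, character(1), 1L),
    label = vapply(parts, `[`, character(1), 2L),
    collection = "custom",
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(
      c(gene_sets$set_id[i], gene_sets$label[i], gene_sets$genes[[i]]),
      collapse = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write genetic-map anchor tables
#'
#' CSV with columns `chromosome`, `bp`, `cM`; anchors must be strictly
#' increasing in both coordinates within each chromosome (validated on
#' read).
#'
#' @param path CSV file.
#' @param map Genetic-map tibble.
#' @return `read_genetic_map()`: the anchor tibble; `write_genetic_map()`:
#'   `path`, invisibly.
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("chromosome", "bp", "cM") %in% names(map)))
  ok <- map %>%
    group_by(.data$chromosome) %>%
    summarise(
      mono = n() >= 2 && all(diff(.data$bp) > 0) && all(diff(.data$cM) > 0),
      .groups = "drop"
    )
  if (!all(ok$mono)) {
    stop_bad_arg("genetic map anchors must be strictly increasing in bp and cM")
  }
  as_tibble(map)
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  readr::write_csv(map, path, progress = FALSE)
  invisible(path)
}

#' Read and write QTL tables
#'
#' CSV with columns `chromosome`, `trait` (PP/PY/FP/FY), `ci_start_cM`,
#' `ci_end_cM`, `peaks_cM` (semicolon-separated peak positions) and
#' `source`. On read, peaks are parsed into a numeric list-column `peaks`.
#'
#' @param path CSV file.
#' @param qtls QTL tibble (with `peaks_cM` string column or `peaks`
#'   list-column).
#' @return `read_qtl_table()`: the QTL tibble with parsed `peaks`;
#'   `write_qtl_table()`: `path`, invisibly.
#' @export
read_qtl_table <- function(path) {
  qtls <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  qtls %>%
    mutate(peaks = lapply(
      strsplit(as.character(.data$peaks_cM), ";", fixed = TRUE), as.numeric
    )) %>%
    as_tibble()
}

#' @rdname read_qtl_table
#' @export
write_qtl_table <- function(qtls, path) {
  if (!"peaks_cM" %in% names(qtls) && "peaks" %in% names(qtls)) {
    qtls$peaks_cM <- vapply(
      qtls$peaks, function(p) paste(format(p, trim = TRUE), collapse = ";"),
      character(1)
    )
  }
  qtls %>%
    select(
      "chromosome", "trait", "ci_start_cM", "ci_end_cM", "peaks_cM", "source"
    ) %>%
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Read and write the family design
#'
#' CSV with columns `family_id`, `high_sample`, `low_sample`: one row per
#' sib family, naming the high- and low-breeding-value sample.
#'
#' @param path CSV file.
#' @param design Design tibble.
#' @return `read_family_design()`: the design tibble;
#'   `write_family_design()`: `path`, invisibly.
#' @export
read_family_design <- function(path) {
  design <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_family_design(design)
  as_tibble(design)
}

#' @rdname read_family_design
#' @export
write_family_design <- function(design, path) {
  readr::write_csv(design, path, progress = FALSE)
  invisible(path)
}

validate_family_design <- function(design) {
  stopifnot(all(c("family_id", "high_sample", "low_sample") %in% names(design)))
  if (nrow(design) < 1) stop_bad_arg("family design needs at least one family")
  ids <- c(design$high_sample, design$low_sample)
  if (anyDuplicated(ids)) {
    stop_bad_arg("sample ids must be unique across the family design")
  }
  invisible(design)
}
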