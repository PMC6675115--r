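#' Run the full screening and prioritization pipeline
#'
#' Executes every stage in order -- call filtering and genotype-matrix
#' assembly, family-contrast screening for common differential SNVs,
#' functional annotation and category summary, gene attachment,
#' over-representation analysis with functional-gene selection, and
#' QTL-proximity candidate selection -- and returns all intermediate tables
#' in one result object. Per-stage record counts are logged as messages.
#' The run is fully deterministic given its inputs; with `out_dir` set,
#' every table is also written as TSV (byte-identical across reruns on
#' identical inputs).
#'
#' @param inputs Named list of input paths (`vcfs`, `design`, `gff`,
#'   `fasta`, `gmt`, `genetic_map`, `qtl_table`), e.g. from
#'   [pipeline_inputs()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the TSV tables.
#' @param quiet Suppress per-stage messages.
#' @return An object of class `extremediff_pipeline`: a list with elements
#'   `genotypes`, `differential`, `annotations`, `category_summary`,
#'   `attachments`, `enrichment`, `functional_genes`, `candidates`,
#'   `counts` and `config`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  for (f in c("vcfs", "design", "gff", "fasta", "gmt", "genetic_map", "qtl_table")) {
    if (is.null(inputs[[f]]) || !all(file.exists(inputs[[f]]))) {
      stop_bad_arg(sprintf("input `%s` is missing or does not exist", f))
    }
  }
  design <- read_family_design(inputs$design)
  models <- read_gene_models(inputs$gff)
  reference <- read_reference(inputs$fasta)
  gene_sets <- read_gmt(inputs$gmt)
  map <- read_genetic_map(inputs$genetic_map)
  qtls <- read_qtl_table(inputs$qtl_table)

  gm <- build_genotype_matrix(inputs$vcfs, design, config)
  say("filter: %d sites x %d samples", nrow(gm), length(attr(gm, "samples")))

  diffs <- common_differential(gm, design)
  say("contrast: %d common differential SNVs", nrow(diffs))

  annotations <- assign_category(
    diffs, models$genes, models$features, reference, config
  )
  category_summary <- if (nrow(annotations) > 0) {
    summarize_categories(annotations)
  } else {
    empty <- tibble(
      category = character(), effect = character(),
      count = integer(), percentage = numeric()
    )
    attr(empty, "total_annotated") <- 0L
    class(empty) <- c("category_summary", class(empty))
    empty
  }
  say("annotate: %d annotated", nrow(annotations))

  attachments <- attach_to_genes(diffs, models$genes, config)
  query <- sort(unique(attachments$gene_id))
  say(
    "attach: %d SNVs retained near %d genes",
    attr(attachments, "n_retained") %||% 0L, length(query)
  )

  enrichment <- run_ora(query, gene_sets, models$genes$gene_id, config)
  functional_genes <- select_functional_genes(
    enrichment, gene_sets, query, config
  )
  say(
    "enrich: %d significant sets, %d functional genes",
    sum(enrichment$significant), nrow(functional_genes)
  )

  candidates <- select_candidates(
    functional_genes, attachments, annotations, models$genes, map, qtls,
    config
  )
  say("prioritize: %d candidate genes", nrow(candidates))

  counts <- tibble(
    stage = c(
      "sites", "common_differential", "annotated", "snvs_attached",
      "genes_attached", "significant_sets", "functional_genes", "candidates"
    ),
    n = c(
      nrow(gm), nrow(diffs), nrow(annotations),
      attr(attachments, "n_retained") %||% 0L, length(query),
      sum(enrichment$significant), nrow(functional_genes), nrow(candidates)
    )
  )

  result <- structure(
    list(
      genotypes = gm, differential = diffs, annotations = annotations,
      category_summary = category_summary, attachments = attachments,
      enrichment = enrichment, functional_genes = functional_genes,
      candidates = candidates, counts = counts, config = config
    ),
    class = "extremediff_pipeline"
  )
  if (!is.null(out_dir)) {
    write_pipeline_tables(result, out_dir)
  }
  result
}

write_pipeline_tables <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  tsv(result$genotypes, "genotype_matrix.tsv")
  tsv(result$differential, "differential_snvs.tsv")
  tsv(result$annotations, "annotations.tsv")
  tsv(as_tibble(result$category_summary), "category_summary.tsv")
  tsv(result$attachments, "attachments.tsv")
  tsv(result$enrichment, "enrichment.tsv")
  tsv(result$functional_genes, "functional_genes.tsv")
  tsv(result$candidates, "candidates.tsv")
  tsv(result$counts, "stage_counts.tsv")
  invisible(out_dir)
}

#' @export
print.extremediff_pipeline <- function(x, ...) {
  cat("<extremediff pipeline result>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-20s %d\n", x$counts$stage[i], x$counts$n[i]))
  }
  invisible(x)
}

#' Tidy the pipeline result into the candidate-gene table
#'
#' @param x An `extremediff_pipeline` object.
#' @param ... Unused.
#' @return The candidate tibble (see [select_candidates()]).
#' @method tidy extremediff_pipeline
#' @export
tidy.extremediff_pipeline <- function(x, ...) {
  x$candidates
}

#' One-row summary of a pipeline run
#'
#' @param x An `extremediff_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble of per-stage record counts.
#' @method glance extremediff_pipeline
#' @export
glance.extremediff_pipeline <- function(x, ...) {
  x$counts %>% tidyr::pivot_wider(names_from = "stage", values_from = "n")
}

#' Plot a category summary as a bar chart
#'
#' @param object A `category_summary` (from [summarize_categories()]).
#' @param ... Unused.
#' @return A ggplot object: percentage of annotated SNVs per functional
#'   category.
#' @method autoplot category_summary
#' @export
autoplot.category_summary <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(is.na(.data$effect)) %>%
    mutate(category = factor(.data$category, levels = rev(.data$category)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$percentage, y = .data$category
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "% of annotated SNVs", y = NULL,
      title = "Functional category distribution"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.category_summary
#' @param object A pipeline result; its differential-SNV category summary
#'   is plotted.
#' @method autoplot extremediff_pipeline
#' @export
autoplot.extremediff_pipeline <- function(object, ...) {
  autoplot(object$category_summary, ...)
}

#' Plot over-representation results
#'
#' @param results Enrichment tibble from [run_ora()].
#' @param top_n Number of top sets to show.
#' @return A ggplot object: -log10 P per gene set, significance coloured.
#' @export
plot_enrichment <- function(results, top_n = 15) {
  df <- results %>%
    dplyr::slice_head(n = top_n) %>%
    mutate(label = factor(.data$label, levels = rev(unique(.data$label))))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_value), y = .data$label, colour = .data$significant
  )) +
    ggplot2::geom_segment(ggplot2::aes(
      x = 0, xend = -log10(.data$p_value), yend = .data$label
    )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = expression(-log[10] ~ P), y = NULL,
      title = "Gene-set over-representation", colour = "P < alpha"
    ) +
    ggplot2::theme_minimal()
}
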