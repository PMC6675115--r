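#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` members of a `K`-gene set when
#' sampling `n` genes without replacement from a background of `N`. This is
#' the one-sided Fisher exact test used for gene-set over-representation.
#' Computed in stable log space via [stats::phyper()].
#'
#' @param k Overlap count(s) between query and set.
#' @param n Query size.
#' @param K Set size within the background.
#' @param N Background (universe) size.
#' @return P value(s) in `[0, 1]`; vectorized over its arguments.
#' @examples
#' ora_test(3, 5, 5, 20) # 1126/15504
#' @export
ora_test <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N
  if (any(bad)) {
    stop_bad_arg("inconsistent margins: need 0 <= k <= min(n, K) and n, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Run over-representation analysis against gene-set collections
#'
#' Tests every gene set with at least one background member for
#' over-representation of the query list, using the raw one-sided
#' hypergeometric P value (no multiple-testing correction by default,
#' matching a raw `P < 0.05` selection criterion; set
#' `config$bh_correction` for Benjamini-Hochberg).
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param gene_sets Gene-set tibble from [read_gmt()].
#' @param background Character vector of universe gene ids (typically all
#'   genes in the gene-model file).
#' @param config A [pipeline_config()].
#' @return A tibble with one row per testable set: `set_id`, `label`,
#'   `collection`, `k`, `n`, `K`, `N`, `p_value` (and `p_adjusted` when
#'   corrected), `significant`; sorted by P value, ties by set id.
#' @export
run_ora <- function(query, gene_sets, background,
                    config = pipeline_config()) {
  background <- unique(background)
  if (length(background) == 0) {
    stop_bad_arg("empty background universe")
  }
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    stop_bad_arg(paste0(
      "query genes outside the background universe: ",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  query <- unique(query)
  N <- length(background)
  n <- length(query)
  res <- gene_sets %>%
    mutate(
      members = lapply(.data$genes, intersect, y = background),
      K = lengths(.data$members),
      k = lengths(lapply(.data$members, intersect, y = query)),
      n = n, N = N
    ) %>%
    filter(.data$K > 0) %>%
    mutate(p_value = ora_test(.data$k, .data$n, .data$K, .data$N))
  if (isTRUE(config$bh_correction)) {
    res <- res %>%
      mutate(
        p_adjusted = p.adjust(.data$p_value, method = "BH"),
        significant = .data$p_adjusted < config$ora_alpha
      )
  } else {
    res <- res %>%
      mutate(significant = .data$p_value < config$ora_alpha)
  }
  res %>%
    select(-"genes", -"members") %>%
    arrange(.data$p_value, .data$set_id)
}

#' Select trait-relevant genes from enrichment results
#'
#' Mechanizes the post-enrichment curation step as the union of two rules:
#' (a) query genes belonging to a significantly enriched set whose label
#' matches at least one relevance keyword (case-insensitive substring), and
#' (b) query genes belonging to any whitelisted pathway set, regardless of
#' significance. Each selected gene carries the rule(s) that admitted it.
#' With both the keyword list and the whitelist empty, rule (a) degenerates
#' to all significant sets (with a warning).
#'
#' @param results Enrichment tibble from [run_ora()].
#' @param gene_sets Gene-set tibble (for memberships).
#' @param query Character vector of query gene ids.
#' @param config A [pipeline_config()].
#' @return A tibble `gene_id`, `admitted_by` (`"significant_keyword"`,
#'   `"whitelist"`, or both, semicolon-joined), `sets` (the admitting set
#'   ids, semicolon-joined), sorted by gene id.
#' @export
select_functional_genes <- function(results, gene_sets, query,
                                    config = pipeline_config()) {
  keywords <- config$relevance_keywords
  whitelist <- config$whitelist_pathways
  if (length(keywords) == 0 && length(whitelist) == 0) {
    warn(paste0(
      "no relevance keywords and no whitelist pathways configured; ",
      "selecting genes from all significant sets"
    ))
  }
  label_matches <- function(labels, patterns) {
    if (length(patterns) == 0) {
      return(rep(FALSE, length(labels)))
    }
    Reduce(`|`, lapply(patterns, function(p) {
      stringr::str_detect(labels, stringr::fixed(p, ignore_case = TRUE))
    }))
  }
  membership <- gene_sets %>%
    select("set_id", "label", "genes") %>%
    tidyr::unnest_longer("genes", values_to = "gene_id") %>%
    filter(.data$gene_id %in% query)

  sig_sets <- results %>% filter(.data$significant)
  rule_a_sets <- if (length(keywords) == 0 && length(whitelist) == 0) {
    sig_sets$set_id
  } else {
    sig_sets$set_id[label_matches(sig_sets$label, keywords)]
  }
  rule_b_sets <- gene_sets$set_id[
    label_matches(gene_sets$label, whitelist)
  ]

  picks <- bind_rows(
    membership %>%
      filter(.data$set_id %in% rule_a_sets) %>%
      mutate(rule = "significant_keyword"),
    membership %>%
      filter(.data$set_id %in% rule_b_sets) %>%
      mutate(rule = "whitelist")
  )
  picks %>%
    group_by(.data$gene_id) %>%
    summarise(
      admitted_by = paste(sort(unique(.data$rule)), collapse = ";"),
      sets = paste(sort(unique(.data$set_id)), collapse = ";"),
      .groups = "drop"
    ) %>%
    arrange(.data$gene_id)
}
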