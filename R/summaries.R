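#' Summarize a per-sample sequencing table
#'
#' Computes the column totals and means of a per-sample sequencing summary
#' (raw reads, mapped reads, per-sample SNV counts, percentages, ...), the
#' arithmetic of the usual "average" row at the bottom of a cohort
#' sequencing table.
#'
#' @param seq_tbl Tibble with one row per sample; all numeric columns are
#'   summarized, any non-numeric columns are ignored.
#' @return A tibble with one row per numeric column: `metric`, `total`,
#'   `mean` (unrounded; round for display with [round_half_up()]).
#' @examples
#' tbl <- tibble::tibble(sample = c("a", "b"), raw_reads = c(10, 20))
#' summarize_sequencing(tbl)
#' @export
summarize_sequencing <- function(seq_tbl) {
  num <- seq_tbl[vapply(seq_tbl, is.numeric, logical(1))]
  if (ncol(num) == 0) {
    stop_bad_arg("no numeric columns to summarize")
  }
  tibble(
    metric = names(num),
    total = unname(vapply(num, sum, numeric(1))),
    mean = unname(vapply(num, mean, numeric(1)))
  )
}
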