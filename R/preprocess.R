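#' Flag unreliable threshold estimates
#'
#' A staircase estimate whose posterior SD exceeds the cutoff is considered
#' unreliable and flagged for exclusion. The rule is strictly greater than:
#' an SD exactly at the cutoff is retained. Rows are flagged, never dropped,
#' so the bookkeeping of [cohort_counts()] stays auditable; the model-fitting
#' stage filters on the flag.
#'
#' @param table Threshold table with an `sd_log10` column (e.g. from
#'   [simulate_cohort()]).
#' @param sd_cutoff_log10 Cutoff in log10 units; default 0.2.
#' @return The table with a logical `excluded` column (re)computed.
#' @examples
#' tb <- tibble::tibble(sd_log10 = c(0.1, 0.2, 0.21))
#' apply_exclusion(tb)$excluded # FALSE FALSE TRUE
#' @export
apply_exclusion <- function(table, sd_cutoff_log10 = 0.2) {
  if (!"sd_log10" %in% names(table)) abort("table has no sd_log10 column")
  if (anyNA(table$sd_log10)) abort("sd_log10 contains missing values")
  if (sd_cutoff_log10 <= 0) abort("sd_cutoff_log10 must be positive")
  dplyr::mutate(table, excluded = .data$sd_log10 > sd_cutoff_log10)
}

#' Cohort bookkeeping counts
#'
#' @param table Threshold table with an `excluded` flag (see
#'   [apply_exclusion()]).
#' @return A one-row tibble: `n_rows`, `n_excluded`, `pct_excluded`
#'   (percentage of rows flagged, rounded to the nearest integer).
#' @examples
#' cohort_counts(apply_exclusion(tibble::tibble(sd_log10 = c(0.1, 0.3))))
#' @export
cohort_counts <- function(table) {
  if (nrow(table) == 0) {
    return(tibble::tibble(n_rows = 0L, n_excluded = 0L, pct_excluded = 0L))
  }
  if (!"excluded" %in% names(table)) abort("table has no excluded column; run apply_exclusion() first")
  n <- nrow(table)
  ne <- sum(table$excluded)
  tibble::tibble(
    n_rows = n,
    n_excluded = as.integer(ne),
    pct_excluded = as.integer(round(100 * ne / n))
  )
}
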