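#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used in published registry summary tables (base [round()] uses
#' round-half-even and would turn 55.555 into 55.55, not 55.56).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places.
#' A zero denominator yields `NA` (rendered as "n/a" in formatted tables);
#' it is not an error because whole table cells can legitimately be empty,
#' e.g. a sponsor class with no device trials.
#'
#' @param numerator,denominator non-negative counts (vectorised).
#' @param decimals decimal places to keep (default 2).
#' @return numeric vector of percentages in `[0, 100]`, `NA` where
#'   `denominator == 0`.
#' @examples
#' percent(168, 428)      # 39.25
#' percent(75, 135)       # 55.56
#' percent(220, 634, 1)   # 34.7
#' @export
percent <- function(numerator, denominator, decimals = 2) {
  stopifnot(length(decimals) == 1, decimals >= 0)
  len <- max(length(numerator), length(denominator))
  numerator <- rep_len(numerator, len)
  denominator <- rep_len(denominator, len)
  out <- rep(NA_real_, len)
  ok <- !is.na(denominator) & denominator > 0
  out[ok] <- round_half_up(100 * numerator[ok] / denominator[ok], decimals)
  out
}

#' @keywords internal
format_percent <- function(p) {
  ifelse(is.na(p), "n/a", formatC(p, format = "fg"))
}

# stop() with a prefix identifying the pipeline stage; used by run_registry_analysis
abort_stage <- function(stage, msg, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(msg, ...)), call. = FALSE)
}
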