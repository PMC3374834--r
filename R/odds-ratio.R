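#' Odds ratios for class membership vs reporting
#'
#' For two binary variables — Y, membership in a target sponsor class, and
#' X, a reporting indicator (results deposited, or at least one outcome
#' listed) — the association is summarised by the odds ratio of their joint
#' distribution:
#'
#' \deqn{OR = \frac{p_{11} p_{00}}{p_{10} p_{01}}
#'          = \frac{n_{11} n_{00}}{n_{10} n_{01}}}
#'
#' where \eqn{p_{yx} = n_{yx} / n} are the empirical joint probabilities;
#' the sample size cancels, so the count and probability forms agree to
#' machine precision. The OR is a sensible effect measure here because it
#' is estimable from non-random samples (registry deposits are clustered by
#' sponsor). Confidence intervals use the Woolf log-OR standard error
#' \eqn{\sqrt{1/n_{11} + 1/n_{10} + 1/n_{01} + 1/n_{00}}} with either a
#' Student-t quantile (df = n - 1, default) or a standard-normal quantile;
#' at registry sample sizes the two are indistinguishable.
#'
#' @name odds-ratio
NULL

#' Build a 2x2 contingency table
#'
#' @param n11,n10,n01,n00 cell counts: first index Y (class membership),
#'   second X (reporting indicator).
#' @return a `contingency_2x2` object.
#' @export
contingency_2x2 <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("empty contingency table", call. = FALSE)
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, 2, byrow = TRUE,
              dimnames = list(Y = c("1", "0"), X = c("1", "0")))
  print(m)
  invisible(x)
}

#' Empirical joint probabilities of a 2x2 table
#'
#' @param table a `contingency_2x2`.
#' @return named numeric vector `p11, p10, p01, p00` summing to 1.
#' @export
joint_probabilities <- function(table) {
  n <- table$n11 + table$n10 + table$n01 + table$n00
  c(p11 = table$n11, p10 = table$n10, p01 = table$n01, p00 = table$n00) / n
}

#' Cross-product odds ratio
#'
#' @param table a `contingency_2x2`.
#' @param correction `"none"` (default; zero off-diagonal cells are an
#'   error, never an infinite estimate) or `"haldane"` (add 0.5 to every
#'   cell).
#' @return the odds ratio, a positive number.
#' @examples
#' odds_ratio(contingency_2x2(10, 5, 2, 8))  # 8
#' @export
odds_ratio <- function(table, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  cells <- c(table$n11, table$n10, table$n01, table$n00)
  if (correction == "haldane") cells <- cells + 0.5
  if (cells[2] == 0 || cells[3] == 0) {
    stop("zero off-diagonal cell: odds ratio undefined (use correction = \"haldane\")",
         call. = FALSE)
  }
  if (cells[1] == 0 || cells[4] == 0) return(0)
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Odds ratio with confidence interval
#'
#' Woolf interval: `log(OR) +- q * SE` with
#' `SE = sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)`; `q` is the two-sided
#' Student-t quantile with `n - 1` degrees of freedom (`method = "t"`,
#' default) or the standard-normal quantile (`method = "normal"`).
#'
#' @param table a `contingency_2x2`.
#' @param level confidence level (default 0.95).
#' @param method `"t"` or `"normal"`.
#' @param correction passed to [odds_ratio()]; Haldane correction, when
#'   selected, is applied to the SE cells as well.
#' @return an `or_result` list: `or`, `ci_low`, `ci_high`, `level`,
#'   `method`.
#' @export
odds_ratio_ci <- function(table, level = 0.95, method = c("t", "normal"),
                          correction = c("none", "haldane")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  or <- odds_ratio(table, correction)
  if (or == 0) stop("zero diagonal cell: log-OR interval undefined", call. = FALSE)
  cells <- c(table$n11, table$n10, table$n01, table$n00)
  if (correction == "haldane") cells <- cells + 0.5
  n <- table$n11 + table$n10 + table$n01 + table$n00
  se <- sqrt(sum(1 / cells))
  q <- if (method == "t") stats::qt(1 - (1 - level) / 2, df = n - 1)
       else stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(or = or,
         ci_low = exp(log(or) - q * se),
         ci_high = exp(log(or) + q * se),
         level = level,
         method = if (method == "t") "woolf-t" else "woolf-normal"),
    class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.4f, %d%% CI (%.4f, %.4f) [%s]\n",
              x$or, round(100 * x$level), x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Build the class-vs-reporting contingency table from a corpus
#'
#' Y = 1 iff the trial's sponsor class equals `target_class`; X = 1 iff the
#' chosen indicator is true. Trials whose class is in `exclude` are removed
#' from *both* margins before counting (default drops `col`, whose member
#' organisations overlap the other classes, and `unclassified`).
#' `restrained = TRUE` keeps only trials satisfying every deposition
#' requirement.
#'
#' @param corpus a corpus tibble with `sponsor_class`.
#' @param target_class the class defining Y = 1.
#' @param indicator `"results"` (results deposited) or `"outcome"` (at
#'   least one outcome listed).
#' @param flags output of [compute_flags()]; required when
#'   `restrained = TRUE`.
#' @param restrained restrict to the all-requirements pool.
#' @param exclude classes removed from both margins.
#' @return a `contingency_2x2`.
#' @export
build_contingency <- function(corpus, target_class,
                              indicator = c("results", "outcome"),
                              flags = NULL, restrained = FALSE,
                              exclude = c("col", "unclassified")) {
  indicator <- match.arg(indicator)
  stopifnot("sponsor_class" %in% names(corpus))
  if (target_class %in% exclude) {
    stop(sprintf("target class '%s' is in the exclusion set", target_class),
         call. = FALSE)
  }
  keep <- !(corpus$sponsor_class %in% exclude)
  if (restrained) {
    if (is.null(flags)) stop("restrained = TRUE requires flags", call. = FALSE)
    stopifnot(nrow(flags) == nrow(corpus))
    keep <- keep & flags$all_requirements
  }
  sub <- corpus[keep, ]
  if (nrow(sub) == 0) {
    stop(if (restrained) "empty restrained pool" else "empty analysis pool",
         call. = FALSE)
  }
  y <- sub$sponsor_class == target_class
  x <- if (indicator == "results") sub$has_results
       else (sub$n_primary_outcomes + sub$n_secondary_outcomes) >= 1
  if (all(y) || !any(y)) {
    stop(sprintf("zero margin for Y (class '%s'): cannot form 2x2 table",
                 target_class), call. = FALSE)
  }
  if (all(x) || !any(x)) {
    stop(sprintf("zero margin for X (indicator '%s'): cannot form 2x2 table",
                 indicator), call. = FALSE)
  }
  contingency_2x2(sum(y & x), sum(y & !x), sum(!y & x), sum(!y & !x))
}

#' Per-class odds-ratio report
#'
#' One OR with CI per target class (default `com`, `gov`, `hos`, `edu`) and
#' indicator (`results` and `outcome`): eight estimates per run.
#'
#' @inheritParams build_contingency
#' @param classes target classes.
#' @param indicators reporting indicators.
#' @param level,method,correction passed to [odds_ratio_ci()].
#' @return tibble: `sponsor_class`, `indicator`, `or`, `ci_low`, `ci_high`,
#'   `level`, `method`, `n` (pool size).
#' @export
class_or_report <- function(corpus, flags = NULL, restrained = FALSE,
                            classes = c("com", "gov", "hos", "edu"),
                            indicators = c("results", "outcome"),
                            exclude = c("col", "unclassified"),
                            level = 0.95, method = "t",
                            correction = "none") {
  grid <- expand.grid(sponsor_class = classes, indicator = indicators,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(sponsor_class, indicator) {
    tab <- build_contingency(corpus, sponsor_class, indicator,
                             flags = flags, restrained = restrained,
                             exclude = exclude)
    ci <- odds_ratio_ci(tab, level = level, method = method,
                        correction = correction)
    tibble::tibble(
      sponsor_class = sponsor_class, indicator = indicator,
      or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
      level = level, method = ci$method,
      n = tab$n11 + tab$n10 + tab$n01 + tab$n00)
  })
  dplyr::bind_rows(rows)
}
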