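#' Reporting-efficiency summary tables
#'
#' Builders for the pipeline's summary tables: yearly results-deposition
#' counts under each requirement, per-class deposition in the restrained
#' pool, outcome-reporting rates, intervention-type efficiency, enrollment
#' summaries, and yearly started/completed plus per-phase counts. Every
#' table carries raw counts next to its percentages so the arithmetic can be
#' re-checked from the printed values alone.
#'
#' @name reporting-tables
NULL

requirement_columns <- function() {
  c(overall = "completed_by_cutoff",  # "Overall" = all completed trials
    fda_regulated = "fda_regulated",
    section_801 = "section_801",
    phase_2_to_4 = "phase_2_to_4",
    with_publications = "has_publication",
    interventional = "interventional",
    all_requirements = "all_requirements")
}

year_bucket_levels <- function(cutoff_year = 2011) {
  c(as.character(seq(cutoff_year, 2001)), "2000 and before", "total")
}

#' Yearly deposition counts under each requirement
#'
#' Restricted to trials completed by the cutoff. For each completion-year
#' bucket (cutoff year down to 2001, then "2000 and before", then a total
#' row) and each requirement column, reports how many trials satisfying
#' that requirement have deposited results, the requirement's total, and
#' the percentage.
#'
#' @param corpus a corpus tibble.
#' @param flags output of [compute_flags()] for the same corpus.
#' @param cutoff snapshot cutoff date (also fixes the latest year bucket).
#' @return a long tibble: `year_bucket`, `requirement`, `with_results`,
#'   `total`, `pct`.
#' @export
yearly_requirement_table <- function(corpus, flags,
                                     cutoff = as.Date("2011-12-31")) {
  stopifnot(nrow(corpus) == nrow(flags))
  keep <- flags$completed_by_cutoff
  sub <- corpus[keep, ]
  fsub <- flags[keep, ]
  buckets <- year_bucket(completion_year(sub))
  levels <- year_bucket_levels(as.integer(format(cutoff, "%Y")))
  reqs <- requirement_columns()

  rows <- lapply(names(reqs), function(rq) {
    in_col <- fsub[[reqs[[rq]]]]
    tab_tot <- table(factor(buckets[in_col], levels = setdiff(levels, "total")))
    tab_res <- table(factor(buckets[in_col & sub$has_results],
                            levels = setdiff(levels, "total")))
    tibble::tibble(
      year_bucket = c(names(tab_tot), "total"),
      requirement = rq,
      with_results = c(as.integer(tab_res), sum(in_col & sub$has_results)),
      total = c(as.integer(tab_tot), sum(in_col)))
  })
  out <- dplyr::bind_rows(rows)
  out$pct <- percent(out$with_results, out$total)
  out$year_bucket <- factor(out$year_bucket, levels = levels)
  dplyr::arrange(out, .data$year_bucket, .data$requirement)
}

#' Per-class deposition in the restrained pool
#'
#' Trials satisfying every deposition requirement (`all_requirements`),
#' grouped by sponsor class: count with results, total, percentage.
#' Classes with no restrained trials are omitted with a warning;
#' unclassified trials are excluded from per-class rows.
#'
#' @param corpus a corpus tibble with a `sponsor_class` column
#'   (see [add_sponsor_class()]).
#' @param flags output of [compute_flags()].
#' @return tibble: `sponsor_class`, `with_results`, `total`, `pct`.
#' @export
class_restrained_table <- function(corpus, flags) {
  stopifnot("sponsor_class" %in% names(corpus), nrow(corpus) == nrow(flags))
  sub <- corpus[flags$all_requirements & corpus$sponsor_class != "unclassified", ]
  present <- intersect(sponsor_classes(), unique(sub$sponsor_class))
  missing <- setdiff(sponsor_classes(), present)
  if (length(missing) > 0) {
    warning(sprintf("no restrained trials for class(es): %s; row(s) omitted",
                    paste(missing, collapse = ", ")))
  }
  out <- sub |>
    dplyr::group_by(sponsor_class = factor(.data$sponsor_class,
                                           levels = present)) |>
    dplyr::summarise(with_results = sum(.data$has_results),
                     total = dplyr::n(), .groups = "drop")
  out$sponsor_class <- as.character(out$sponsor_class)
  out$with_results <- as.integer(out$with_results)
  out$pct <- percent(out$with_results, out$total)
  out
}

#' Outcome reporting by sponsor class
#'
#' Operates on the full corpus (no restraints): per class, the number and
#' percentage of trials listing at least one outcome (primary + secondary
#' count >= 1) and more than one outcome.
#'
#' @param corpus a corpus tibble with `sponsor_class`.
#' @return tibble: `sponsor_class`, `class_total`, `n_at_least_one`,
#'   `pct_at_least_one`, `n_more_than_one`, `pct_more_than_one`.
#' @export
outcome_table <- function(corpus) {
  stopifnot("sponsor_class" %in% names(corpus))
  n_out <- corpus$n_primary_outcomes + corpus$n_secondary_outcomes
  sub <- tibble::tibble(sponsor_class = corpus$sponsor_class,
                        ge1 = n_out >= 1, gt1 = n_out > 1)
  sub <- sub[sub$sponsor_class != "unclassified", ]
  out <- sub |>
    dplyr::group_by(.data$sponsor_class) |>
    dplyr::summarise(class_total = dplyr::n(),
                     n_at_least_one = sum(.data$ge1),
                     n_more_than_one = sum(.data$gt1), .groups = "drop")
  out$pct_at_least_one <- percent(out$n_at_least_one, out$class_total)
  out$pct_more_than_one <- percent(out$n_more_than_one, out$class_total)
  out[, c("sponsor_class", "class_total", "n_at_least_one", "pct_at_least_one",
          "n_more_than_one", "pct_more_than_one")]
}

#' Intervention-type counts and results-reporting efficiency
#'
#' For each sponsor class and each of the three most common intervention
#' types (Drug, Procedure, Device): the number of the class's trials using
#' that type, its share of the class's interventional trials, and the
#' results-reporting *efficiency* — the percentage of those trials with
#' deposited results. A trial with several intervention types contributes
#' to each of its types (columns need not sum to the interventional total).
#' Cells with no trials report `NA` ("n/a") efficiency.
#'
#' @param corpus a corpus tibble with `sponsor_class`.
#' @param types intervention types to tabulate.
#' @param share_denominator `"interventional"` (default: share is of the
#'   class's interventional trials) or `"all"` (of all class trials).
#' @return tibble: `sponsor_class`, `intervention`, `n_trials`, `share_pct`,
#'   `efficiency_pct`.
#' @export
intervention_table <- function(corpus,
                               types = c("Drug", "Procedure", "Device"),
                               share_denominator = c("interventional", "all")) {
  stopifnot("sponsor_class" %in% names(corpus))
  share_denominator <- match.arg(share_denominator)
  sub <- corpus[corpus$sponsor_class != "unclassified", ]
  classes <- intersect(sponsor_classes(), unique(sub$sponsor_class))
  interventional <- !is.na(sub$study_type) & sub$study_type == "Interventional"
  grid <- expand.grid(sponsor_class = classes, intervention = types,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(sponsor_class, intervention) {
    in_class <- sub$sponsor_class == sponsor_class
    has_type <- vapply(sub$intervention_types,
                       function(tt) intervention %in% tt, logical(1))
    denom <- if (share_denominator == "interventional") {
      sum(in_class & interventional)
    } else {
      sum(in_class)
    }
    n <- sum(in_class & has_type)
    tibble::tibble(
      sponsor_class = sponsor_class, intervention = intervention,
      n_trials = n,
      share_pct = percent(n, denom),
      efficiency_pct = percent(sum(in_class & has_type & sub$has_results), n))
  })
  dplyr::bind_rows(rows)
}

#' Enrollment summaries per class and stratum
#'
#' Base population: trials with overall status `Completed` or
#' `Active, not recruiting`. Strata narrow it progressively: all such
#' trials; those reporting at least one outcome; those with deposited
#' results; results plus interventional design. Trials lacking an
#' enrollment value are excluded from each stratum. Enrollment anomalies
#' (0 and the sentinel 99999999) are *not* filtered: the unrestricted
#' stratum deliberately shows how they inflate maxima and averages.
#'
#' @param corpus a corpus tibble with `sponsor_class`.
#' @return tibble: `stratum`, `sponsor_class`, `n_trials`, `max_enrollment`,
#'   `average_enrollment` (total / n, 2 decimals), `total_participants`.
#' @export
enrollment_table <- function(corpus) {
  stopifnot("sponsor_class" %in% names(corpus))
  base <- corpus[!is.na(corpus$overall_status) &
                   corpus$overall_status %in%
                   c("Completed", "Active, not recruiting") &
                   corpus$sponsor_class != "unclassified", ]
  n_out <- base$n_primary_outcomes + base$n_secondary_outcomes
  strata <- list(
    all = rep(TRUE, nrow(base)),
    with_outcome = n_out >= 1,
    with_results = base$has_results,
    results_interventional = base$has_results &
      !is.na(base$study_type) & base$study_type == "Interventional")
  rows <- purrr::imap(strata, function(keep, label) {
    sub <- base[keep & !is.na(base$enrollment), ]
    if (nrow(sub) == 0) return(NULL)
    sub |>
      dplyr::group_by(sponsor_class = .data$sponsor_class) |>
      dplyr::summarise(
        n_trials = dplyr::n(),
        max_enrollment = max(.data$enrollment),
        total_participants = sum(as.numeric(.data$enrollment)),
        .groups = "drop") |>
      dplyr::mutate(
        stratum = label,
        average_enrollment = round_half_up(
          .data$total_participants / .data$n_trials, 2))
  })
  out <- dplyr::bind_rows(rows)
  out[, c("stratum", "sponsor_class", "n_trials", "max_enrollment",
          "average_enrollment", "total_participants")]
}

#' Trials started and completed per year
#'
#' @param corpus a corpus tibble.
#' @return tibble: `year`, `n_started`, `n_completed` (0 where none);
#'   trials without the relevant date are excluded from that count.
#' @export
yearly_activity <- function(corpus) {
  started <- partial_date_year(corpus$start_date)
  completed <- completion_year(corpus)
  years <- sort(unique(c(started, completed)))
  years <- years[!is.na(years)]
  tibble::tibble(
    year = years,
    n_started = as.integer(table(factor(started, levels = years))),
    n_completed = as.integer(table(factor(completed, levels = years))))
}

#' Phase distribution per sponsor class
#'
#' A multi-phase trial ("Phase 2/Phase 3") contributes to each of its
#' phases; trials without an explicit phase are excluded.
#'
#' @param corpus a corpus tibble with `sponsor_class`.
#' @return tibble: `sponsor_class`, `phase` (1-4), `n_trials`.
#' @export
phase_distribution <- function(corpus) {
  stopifnot("sponsor_class" %in% names(corpus))
  ph <- parse_phase(corpus$phase_raw)
  long <- tibble::tibble(
    sponsor_class = rep(corpus$sponsor_class, lengths(ph$phases)),
    phase = unlist(ph$phases))
  long <- long[long$sponsor_class != "unclassified", ]
  classes <- intersect(sponsor_classes(), unique(corpus$sponsor_class))
  grid <- expand.grid(sponsor_class = classes, phase = 1:4,
                      stringsAsFactors = FALSE)
  counts <- dplyr::count(long, .data$sponsor_class, .data$phase,
                         name = "n_trials")
  out <- dplyr::left_join(tibble::as_tibble(grid), counts,
                          by = c("sponsor_class", "phase"))
  out$n_trials[is.na(out$n_trials)] <- 0L
  dplyr::arrange(out, .data$sponsor_class, .data$phase)
}

#' Write a table as CSV and aligned plain text
#'
#' @param df a tibble.
#' @param path_base output path without extension; writes `<base>.csv` and
#'   `<base>.txt`. `NA` percentages print as "n/a" in the text form.
#' @return invisibly, the two paths written.
#' @export
write_table_outputs <- function(df, path_base) {
  csv <- paste0(path_base, ".csv")
  txt <- paste0(path_base, ".txt")
  readr::write_csv(df, csv, na = "n/a")
  fmt <- df
  for (cl in names(fmt)) {
    if (is.numeric(fmt[[cl]])) {
      fmt[[cl]] <- ifelse(is.na(fmt[[cl]]), "n/a",
                          formatC(fmt[[cl]], format = "fg", digits = 15))
    }
  }
  m <- as.matrix(fmt)
  m <- rbind(colnames(m), m)
  widths <- apply(nchar(m, type = "width"), 2, max)
  lines <- apply(m, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
  writeLines(trimws(lines, "right"), txt)
  invisible(c(csv, txt))
}
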