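#' Results-deposition requirement cascade
#'
#' Summary results must be deposited for trials that are completed, FDA
#' regulated (specifically covered by Section 801 of the FDAAA), in an
#' explicit phase 2-4, carry a peer-reviewed publication reference, and are
#' interventional. [compute_flags()] evaluates each of these per trial plus
#' their conjunction (`all_requirements`, the "restrained pool"). Flags are
#' pure functions of the record and the cutoff date; absent oversight flags
#' evaluate `FALSE` because registry counts of "FDA regulated" trials are
#' counts of affirmative assignments, not of non-denials.
#'
#' @name requirement-cascade
NULL

#' Parse a registry phase string
#'
#' Extracts every phase number 1-4 named in the string. `"N/A"`, absent
#' values and `"Early Phase 1"` (an exploratory designation, not a numbered
#' phase) yield a non-explicit, empty phase set.
#'
#' @param phase_raw character vector of phase strings.
#' @return a tibble with list-column `phases` (integer vectors) and logical
#'   `explicit`.
#' @examples
#' parse_phase("Phase 2/Phase 3")  # phases {2,3}, explicit
#' parse_phase("N/A")              # empty, not explicit
#' @export
parse_phase <- function(phase_raw) {
  x <- tolower(as.character(phase_raw))
  # drop the exploratory designation before looking for numbered phases
  x <- stringi::stri_replace_all_fixed(x, "early phase 1", "")
  found <- stringi::stri_extract_all_regex(x, "phase\\s*([1-4])")
  phases <- lapply(found, function(f) {
    if (length(f) == 1 && is.na(f)) return(integer(0))
    sort(unique(as.integer(stringi::stri_extract_last_regex(f, "[1-4]"))))
  })
  phases[is.na(x)] <- list(integer(0))
  tibble::tibble(phases = phases,
                 explicit = lengths(phases) > 0)
}

#' Completion year of each trial
#'
#' @param corpus a corpus tibble.
#' @return integer vector of completion years, `NA` where the record has no
#'   completion date.
#' @seealso [year_bucket()] for the reporting buckets.
#' @export
completion_year <- function(corpus) {
  partial_date_year(corpus$completion_date)
}

#' Report-time year bucket
#'
#' Years up to 2000 are pooled into a single `"2000 and before"` bucket;
#' later years print as themselves.
#'
#' @param year integer vector of years.
#' @return character vector of bucket labels, `NA` preserved.
#' @export
year_bucket <- function(year) {
  ifelse(is.na(year), NA_character_,
         ifelse(year <= 2000, "2000 and before", as.character(year)))
}

#' Compute the requirement flags for every trial
#'
#' * `completed_by_cutoff` — overall status is exactly `Completed` *and* a
#'   completion date exists *and* its latest possible calendar day is on or
#'   before `cutoff` (month-granular dates are resolved conservatively, so a
#'   trial that may have completed after the snapshot is excluded).
#' * `fda_regulated`, `section_801` — the record affirms the flag.
#' * `phase_2_to_4` — the explicit phase set intersects \{2,3,4\}
#'   (`phase_rule = "intersect"`, default, so `"Phase 1/Phase 2"`
#'   qualifies) or has minimum phase at least 2 (`phase_rule = "min"`).
#' * `has_publication` — at least one attached reference.
#' * `interventional` — study type is `Interventional`.
#' * `all_requirements` — conjunction of all six.
#'
#' @param corpus a corpus tibble.
#' @param cutoff snapshot cutoff `Date` (default `2011-12-31`).
#' @param phase_rule `"intersect"` or `"min"`, see above.
#' @return a tibble of one logical row per trial, columns as above, plus
#'   `nct_id`.
#' @export
compute_flags <- function(corpus, cutoff = as.Date("2011-12-31"),
                          phase_rule = c("intersect", "min")) {
  phase_rule <- match.arg(phase_rule)
  ph <- parse_phase(corpus$phase_raw)
  phase_ok <- if (phase_rule == "intersect") {
    vapply(ph$phases, function(p) any(p >= 2), logical(1))
  } else {
    vapply(ph$phases, function(p) length(p) > 0 && min(p) >= 2, logical(1))
  }
  last_day <- partial_date_last_day(corpus$completion_date)
  completed <- !is.na(corpus$overall_status) &
    corpus$overall_status == "Completed" &
    !is.na(last_day) & last_day <= cutoff
  flags <- tibble::tibble(
    nct_id = corpus$nct_id,
    completed_by_cutoff = completed,
    fda_regulated = !is.na(corpus$is_fda_regulated) & corpus$is_fda_regulated,
    section_801 = !is.na(corpus$is_section_801) & corpus$is_section_801,
    phase_2_to_4 = ph$explicit & phase_ok,
    has_publication = corpus$n_references >= 1,
    interventional = !is.na(corpus$study_type) &
      corpus$study_type == "Interventional")
  flags$all_requirements <- flags$completed_by_cutoff & flags$fda_regulated &
    flags$section_801 & flags$phase_2_to_4 & flags$has_publication &
    flags$interventional
  flags
}
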