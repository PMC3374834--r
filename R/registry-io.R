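#' Trial records and corpora
#'
#' A trial record is one row of a *corpus* tibble with these columns:
#'
#' * `nct_id` — registry identifier, `"NCT"` + 8 digits, unique in a corpus.
#' * `lead_sponsor_name` — free text, possibly non-ASCII (sponsors are filed
#'   in many languages).
#' * `agency_class` — the registry's own sponsor label: `Industry`, `NIH`,
#'   `U.S. Fed` or `Other`.
#' * `overall_status` — controlled vocabulary (`Completed`,
#'   `Active, not recruiting`, `Recruiting`, `Terminated`, `Withdrawn`, ...);
#'   unknown values are preserved verbatim, never coerced at parse time.
#' * `start_date`, `completion_date` — partial dates (see
#'   [parse_partial_date()]); `NA` = absent.
#' * `phase_raw` — phase string as recorded (`"Phase 2/Phase 3"`, `"N/A"`),
#'   `NA` = absent.
#' * `study_type`, `primary_purpose` — design descriptors, `NA` = absent.
#' * `intervention_types` — list-column of character vectors (a trial can
#'   combine e.g. Drug and Device arms).
#' * `is_fda_regulated`, `is_section_801` — logical, `NA` = not stated.
#' * `has_results` — `TRUE` iff a deposited summary-results section exists
#'   (a structural test: the element is present, no judgement of its
#'   completeness).
#' * `n_primary_outcomes`, `n_secondary_outcomes`, `n_references` — counts
#'   of the corresponding record elements.
#' * `enrollment` — participant count, `NA` = absent. Real registry data
#'   contains anomalies (0 and the sentinel 99999999); they are kept as-is.
#' * `enrollment_type` — `Actual` or `Anticipated`, `NA` = absent.
#' * `number_of_arms` — `NA` = absent.
#'
#' @name trial-corpus
NULL

corpus_columns <- function() {
  c("nct_id", "lead_sponsor_name", "agency_class", "overall_status",
    "start_date", "completion_date", "phase_raw", "study_type",
    "intervention_types", "primary_purpose", "is_fda_regulated",
    "is_section_801", "has_results", "n_primary_outcomes",
    "n_secondary_outcomes", "n_references", "enrollment", "enrollment_type",
    "number_of_arms")
}

empty_corpus <- function() {
  tibble::tibble(
    nct_id = character(), lead_sponsor_name = character(),
    agency_class = character(), overall_status = character(),
    start_date = character(), completion_date = character(),
    phase_raw = character(), study_type = character(),
    intervention_types = list(), primary_purpose = character(),
    is_fda_regulated = logical(), is_section_801 = logical(),
    has_results = logical(), n_primary_outcomes = integer(),
    n_secondary_outcomes = integer(), n_references = integer(),
    enrollment = integer(), enrollment_type = character(),
    number_of_arms = integer())
}

xml_text1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
}

yes_no <- function(x) {
  if (is.na(x)) return(NA)
  tolower(stringi::stri_trim_both(x)) == "yes"
}

#' Read one trial record from registry XML
#'
#' Parses a single `clinical_study` document in the ClinicalTrials.gov
#' public-XML dialect. Absent optional elements become `NA` — the reader
#' never invents defaults. Results presence is structural: `has_results`
#' is `TRUE` iff a `<clinical_results>` element exists.
#'
#' @param path path to an XML file (or anything [xml2::read_xml()] accepts).
#' @return a one-row corpus tibble (see [trial-corpus]).
#' @seealso [read_corpus()] for a directory of records.
#' @export
read_registry_xml <- function(path) {
  doc <- xml2::read_xml(path, encoding = "UTF-8")
  root <- xml2::xml_name(doc)
  if (root != "clinical_study") {
    stop(sprintf("unrecognised root element <%s> (expected <clinical_study>)",
                 root), call. = FALSE)
  }
  nct_id <- xml_text1(doc, "./id_info/nct_id")
  if (is.na(nct_id) || !nzchar(nct_id)) {
    stop("record rejected: missing nct_id (identifier unknown)",
         call. = FALSE)
  }

  enr_node <- xml2::xml_find_first(doc, "./enrollment")
  enrollment <- NA_integer_
  enrollment_type <- NA_character_
  if (!inherits(enr_node, "xml_missing")) {
    enrollment <- suppressWarnings(as.integer(xml2::xml_text(enr_node)))
    ty <- xml2::xml_attr(enr_node, "type")
    enrollment_type <- if (is.na(ty)) NA_character_ else ty
  }

  n_arms <- xml_text1(doc, "./number_of_arms")

  tibble::tibble(
    nct_id = nct_id,
    lead_sponsor_name = xml_text1(doc, "./sponsors/lead_sponsor/agency"),
    agency_class = xml_text1(doc, "./sponsors/lead_sponsor/agency_class"),
    overall_status = xml_text1(doc, "./overall_status"),
    start_date = parse_partial_date(xml_text1(doc, "./start_date")),
    completion_date = parse_partial_date(xml_text1(doc, "./completion_date")),
    phase_raw = xml_text1(doc, "./phase"),
    study_type = xml_text1(doc, "./study_type"),
    intervention_types = list(xml2::xml_text(
      xml2::xml_find_all(doc, "./intervention/intervention_type"))),
    primary_purpose = xml_text1(doc, "./study_design_info/primary_purpose"),
    is_fda_regulated = yes_no(xml_text1(doc, "./oversight_info/is_fda_regulated")),
    is_section_801 = yes_no(xml_text1(doc, "./oversight_info/is_section_801")),
    has_results = length(xml2::xml_find_all(doc, "./clinical_results")) > 0,
    n_primary_outcomes = length(xml2::xml_find_all(doc, "./primary_outcome")),
    n_secondary_outcomes = length(xml2::xml_find_all(doc, "./secondary_outcome")),
    n_references = length(xml2::xml_find_all(doc, "./reference")),
    enrollment = enrollment,
    enrollment_type = enrollment_type,
    number_of_arms = if (is.na(n_arms)) NA_integer_ else
      suppressWarnings(as.integer(n_arms))
  )
}

#' Read a directory of registry XML files
#'
#' One XML file per trial. Malformed files are reported, not fatal; the
#' corpus is returned sorted by `nct_id` for deterministic downstream
#' output. Duplicate identifiers are an error (they would silently corrupt
#' every downstream count).
#'
#' @param dir directory containing `.xml` files.
#' @return a list with `corpus` (tibble, sorted by `nct_id`) and `failures`
#'   (tibble with `file` and `reason` for each unparseable file).
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (length(files) == 0) {
    warning(sprintf("no XML files found in '%s'; returning empty corpus", dir))
    return(list(corpus = empty_corpus(),
                failures = tibble::tibble(file = character(),
                                          reason = character())))
  }
  records <- vector("list", length(files))
  fail_file <- character()
  fail_reason <- character()
  for (i in seq_along(files)) {
    rec <- tryCatch(read_registry_xml(files[[i]]), error = function(e) e)
    if (inherits(rec, "error")) {
      fail_file <- c(fail_file, basename(files[[i]]))
      fail_reason <- c(fail_reason, conditionMessage(rec))
    } else {
      records[[i]] <- rec
    }
  }
  corpus <- dplyr::bind_rows(records)
  if (nrow(corpus) > 0) {
    dup <- corpus$nct_id[duplicated(corpus$nct_id)]
    if (length(dup) > 0) {
      stop(sprintf("duplicate nct_id in corpus: %s",
                   paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
    corpus <- dplyr::arrange(corpus, .data$nct_id)
  } else {
    corpus <- empty_corpus()
  }
  list(corpus = corpus,
       failures = tibble::tibble(file = fail_file, reason = fail_reason))
}

#' Write a corpus as delimited text
#'
#' UTF-8 CSV (RFC 4180 quoting via readr). Partial dates are already
#' ISO-like strings; the intervention-type list-column is serialised as a
#' `|`-joined field. [read_tabular()] inverts the encoding exactly.
#'
#' @param corpus a corpus tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(corpus, path) {
  flat <- corpus
  flat$intervention_types <- vapply(
    corpus$intervention_types,
    function(x) paste(x, collapse = "|"), character(1))
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' Read a corpus written by [write_tabular()]
#'
#' @param path CSV file produced by [write_tabular()].
#' @return a corpus tibble.
#' @export
read_tabular <- function(path) {
  flat <- readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      nct_id = "c", lead_sponsor_name = "c", agency_class = "c",
      overall_status = "c", start_date = "c", completion_date = "c",
      phase_raw = "c", study_type = "c", intervention_types = "c",
      primary_purpose = "c", is_fda_regulated = "l", is_section_801 = "l",
      has_results = "l", n_primary_outcomes = "i", n_secondary_outcomes = "i",
      n_references = "i", enrollment = "i", enrollment_type = "c",
      number_of_arms = "i"))
  flat$intervention_types <- lapply(flat$intervention_types, function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else strsplit(x, "|", fixed = TRUE)[[1]]
  })
  flat[, corpus_columns()]
}
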