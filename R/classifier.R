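#' Sponsor classification
#'
#' Registry records label each lead sponsor with only a four-way agency
#' class (`Industry`, `NIH`, `U.S. Fed`, `Other`), which lumps universities,
#' hospitals, collaborations and foreign governments into one "Other"
#' bucket. The classifier here refines that into five institutional
#' classes — `edu` (research/educational institutions), `com` (for-profit
#' health-care companies), `gov` (national and government organisations),
#' `hos` (hospitals & clinics) and `col` (collaborations) — by matching
#' prioritised multilingual keyword dictionaries against the sponsor name,
#' falling back on the registry's agency class when no keyword matches.
#' Names that match nothing and carry agency class `Other` stay
#' `unclassified`.
#'
#' @name sponsor-classification
NULL

sponsor_classes <- function() c("edu", "com", "gov", "hos", "col")

#' Normalise a sponsor name for keyword matching
#'
#' Unicode compatibility normalisation (NFKC), case folding, whitespace
#' collapse and trimming. Diacritics are preserved so multilingual keywords
#' ("Hôpitaux", "Klinik", "Università") match exactly. Idempotent.
#'
#' @param x character vector of raw sponsor names.
#' @return normalised character vector (empty input stays empty).
#' @examples
#' normalize_name("  PFIZER  Inc.")  # "pfizer inc."
#' @export
normalize_name <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

regex_escape <- function(x) {
  stringi::stri_replace_all_regex(x, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1")
}

# keyword -> regex: match at word boundaries over the normalised name.
# A trailing "." in the keyword is optional when the dotless form is
# followed by a boundary ("acme corp" matches "corp."), but the dotless
# stem never matches inside a longer word ("include" does not match "inc.").
keyword_pattern <- function(kw) {
  trailing_dot <- stringi::stri_detect_regex(kw, "\\.$")
  stem <- stringi::stri_replace_all_regex(kw, "\\.+$", "")
  ifelse(trailing_dot,
         paste0("(?<![\\p{L}\\p{N}])", regex_escape(stem),
                "(\\.|(?![\\p{L}\\p{N}]))"),
         paste0("(?<![\\p{L}\\p{N}])", regex_escape(kw),
                "(?![\\p{L}\\p{N}])"))
}

#' Load a sponsor-class keyword dictionary
#'
#' Reads the YAML dictionary format: a `priority` list (total order over
#' classes, highest priority first), a `fallback` map from registry agency
#' class to sponsor class, and per-class keyword lists. The packaged default
#' dictionary is used when `path` is omitted.
#'
#' @param path path to a dictionary YAML file, or `NULL` for the packaged
#'   default.
#' @param fold_diacritics if `TRUE`, both keywords and names are stripped of
#'   diacritics before matching (default `FALSE`: "Hôpitaux" and "Hopitaux"
#'   are then distinct).
#' @return a `sponsor_dictionary` object.
#' @export
load_sponsor_dictionary <- function(path = NULL, fold_diacritics = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "sponsor_dictionary.yaml",
                        package = "ctrreport", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  for (field in c("priority", "fallback", "classes")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("dictionary file lacks '%s' section", field), call. = FALSE)
    }
  }
  priority <- as.character(raw$priority)
  classes <- names(raw$classes)
  if (!setequal(priority, classes)) {
    stop("dictionary 'priority' must list exactly the classes defined",
         call. = FALSE)
  }
  fallback <- vapply(raw$fallback, as.character, character(1))
  needed <- c("Industry", "NIH", "U.S. Fed", "Other")
  if (!all(needed %in% names(fallback))) {
    stop(sprintf("fallback map must cover: %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  keywords <- lapply(raw$classes, function(cl) {
    kw <- normalize_name(as.character(cl$keywords))
    if (fold_diacritics) kw <- fold_ascii(kw)
    # longest first so the reported match is the most specific keyword
    kw[order(-nchar(kw), kw)]
  })
  all_kw <- unlist(keywords, use.names = FALSE)
  if (anyDuplicated(all_kw)) {
    stop(sprintf("keyword assigned to more than one class: %s",
                 paste(unique(all_kw[duplicated(all_kw)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(priority = priority,
         fallback = fallback,
         keywords = keywords,
         patterns = lapply(keywords, keyword_pattern),
         fold_diacritics = fold_diacritics),
    class = "sponsor_dictionary")
}

fold_ascii <- function(x) stringi::stri_trans_general(x, "Latin-ASCII")

#' @export
print.sponsor_dictionary <- function(x, ...) {
  cat("Sponsor-class keyword dictionary\n")
  cat("  priority:", paste(x$priority, collapse = " > "), "\n")
  for (cl in x$priority) {
    cat(sprintf("  %s: %d keywords\n", cl, length(x$keywords[[cl]])))
  }
  cat("  fallback:",
      paste(sprintf("%s->%s", names(x$fallback), x$fallback), collapse = ", "),
      "\n")
  invisible(x)
}

# class assignment from keywords alone; NA where no keyword matches
match_keyword_class <- function(names_norm, dict) {
  out <- rep(NA_character_, length(names_norm))
  for (cl in dict$priority) {
    open <- is.na(out)
    if (!any(open)) break
    hit <- rep(FALSE, sum(open))
    for (pat in dict$patterns[[cl]]) {
      hit <- hit | stringi::stri_detect_regex(names_norm[open], pat)
    }
    out[open][hit] <- cl
  }
  out
}

#' Classify sponsors
#'
#' Assigns each sponsor name to a class: the highest-priority class with a
#' matching keyword, else the fallback for the record's agency class
#' (`Other` falls back to `"unclassified"`). Total and deterministic.
#'
#' @param name character vector of raw lead-sponsor names.
#' @param agency character vector of registry agency classes (recycled if
#'   length 1).
#' @param dict a [load_sponsor_dictionary()] object (default: packaged
#'   dictionary).
#' @return character vector of class labels in
#'   `{edu, com, gov, hos, col, unclassified}`.
#' @examples
#' d <- load_sponsor_dictionary()
#' classify_sponsor("University Hospital Basel", "Other", d)  # "hos"
#' classify_sponsor("Acme Corp.", "Industry", d)              # "com"
#' @export
classify_sponsor <- function(name, agency, dict = load_sponsor_dictionary()) {
  if (length(agency) == 1) agency <- rep(agency, length(name))
  stopifnot(length(name) == length(agency))
  nm <- normalize_name(name)
  if (dict$fold_diacritics) nm <- fold_ascii(nm)
  cls <- match_keyword_class(nm, dict)
  fb <- unname(dict$fallback[agency])
  fb[is.na(fb)] <- "unclassified"  # unknown agency labels get no fallback
  ifelse(is.na(cls), fb, cls)
}

#' Classify a whole corpus
#'
#' @param corpus a corpus tibble (see [trial-corpus]).
#' @param dict a sponsor dictionary.
#' @return a list with `assignments` (tibble `nct_id`, `sponsor_class`) and
#'   `summary` (per class: `n` trials and `share_pct` of the corpus,
#'   unclassified included in the denominator).
#' @export
classify_corpus <- function(corpus, dict = load_sponsor_dictionary()) {
  cls <- classify_sponsor(corpus$lead_sponsor_name, corpus$agency_class, dict)
  assignments <- tibble::tibble(nct_id = corpus$nct_id, sponsor_class = cls)
  lev <- c(sponsor_classes(), "unclassified")
  counts <- table(factor(cls, levels = lev))
  summary <- tibble::tibble(
    sponsor_class = lev,
    n = as.integer(counts),
    share_pct = percent(as.integer(counts), nrow(corpus)))
  list(assignments = assignments, summary = summary)
}

#' Append a `sponsor_class` column to a corpus
#'
#' @inheritParams classify_corpus
#' @return `corpus` with a `sponsor_class` column.
#' @export
add_sponsor_class <- function(corpus, dict = load_sponsor_dictionary()) {
  corpus$sponsor_class <- classify_sponsor(
    corpus$lead_sponsor_name, corpus$agency_class, dict)
  corpus
}
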