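#' Partial dates
#'
#' Registry records date trials at month-year granularity ("December 2011"),
#' occasionally with a day ("June 4, 2008") and rarely as a bare year.
#' Partial dates are carried as ISO-like strings: `"2011"`, `"2011-12"`,
#' `"2008-06-04"`; `NA` means absent. Helpers below parse the registry's
#' textual form and compare partial dates against a calendar cutoff.
#'
#' @name partial-dates
NULL

.month_names <- c("january", "february", "march", "april", "may", "june",
                  "july", "august", "september", "october", "november",
                  "december")

#' Parse a registry date string into a partial date
#'
#' Accepts `"Month YYYY"`, `"Month DD, YYYY"` and bare `"YYYY"`; anything
#' else (including `NA` and empty strings) parses to `NA`.
#'
#' @param x character vector of registry date strings.
#' @return character vector of partial dates (`"YYYY"`, `"YYYY-MM"` or
#'   `"YYYY-MM-DD"`), `NA` where unparseable.
#' @examples
#' parse_partial_date("December 2011")   # "2011-12"
#' parse_partial_date("June 4, 2008")    # "2008-06-04"
#' parse_partial_date("2009")            # "2009"
#' @export
parse_partial_date <- function(x) {
  x <- stringi::stri_trim_both(as.character(x))
  out <- rep(NA_character_, length(x))

  # Month DD, YYYY
  m <- stringi::stri_match_first_regex(
    x, "^([A-Za-z]+)\\s+(\\d{1,2}),\\s*(\\d{4})$")
  hit <- !is.na(m[, 1])
  if (any(hit)) {
    mon <- match(tolower(m[hit, 2]), .month_names)
    ok <- !is.na(mon)
    idx <- which(hit)[ok]
    out[idx] <- sprintf("%s-%02d-%02d", m[idx, 4], mon[ok],
                        as.integer(m[idx, 3]))
  }

  # Month YYYY
  m <- stringi::stri_match_first_regex(x, "^([A-Za-z]+)\\s+(\\d{4})$")
  hit <- !is.na(m[, 1]) & is.na(out)
  if (any(hit)) {
    mon <- match(tolower(m[hit, 2]), .month_names)
    ok <- !is.na(mon)
    idx <- which(hit)[ok]
    out[idx] <- sprintf("%s-%02d", m[idx, 3], mon[ok])
  }

  # bare year
  hit <- is.na(out) & stringi::stri_detect_regex(x, "^\\d{4}$") & !is.na(x)
  out[hit] <- x[hit]
  out
}

#' Year component of a partial date
#'
#' @param pd partial-date character vector.
#' @return integer vector of years, `NA` where absent.
#' @export
partial_date_year <- function(pd) {
  as.integer(substr(pd, 1, 4))
}

#' Latest calendar day a partial date can denote
#'
#' `"2011"` maps to 2011-12-31, `"2011-06"` to 2011-06-30. Used for the
#' conservative "completed by cutoff" rule: a month-granular completion date
#' counts as on-or-before the cutoff only if even its last possible day is.
#'
#' @param pd partial-date character vector.
#' @return a `Date` vector, `NA` where `pd` is absent.
#' @export
partial_date_last_day <- function(pd) {
  n <- nchar(pd)
  out <- rep(as.Date(NA), length(pd))
  full <- !is.na(pd) & n == 10
  out[full] <- as.Date(pd[full])
  ym <- !is.na(pd) & n == 7
  if (any(ym)) {
    first <- as.Date(paste0(pd[ym], "-01"))
    # last day of month = day before the first of next month
    out[ym] <- seq_next_month(first) - 1
  }
  yr <- !is.na(pd) & n == 4
  if (any(yr)) out[yr] <- as.Date(paste0(pd[yr], "-12-31", recycle0 = TRUE))
  out
}

# vectorised "first day of the following month"
seq_next_month <- function(d) {
  lt <- as.POSIXlt(d)
  lt$mon <- lt$mon + 1L
  lt$mday <- 1L
  as.Date(lt)
}

#' Render a partial date in the registry's textual form
#'
#' Inverse of [parse_partial_date()]: `"2011-12"` becomes `"December 2011"`,
#' `"2008-06-04"` becomes `"June 4, 2008"`, `"2009"` stays `"2009"`.
#'
#' @param pd partial-date character vector.
#' @return character vector, `NA` where `pd` is absent.
#' @export
format_partial_date <- function(pd) {
  out <- rep(NA_character_, length(pd))
  n <- nchar(pd)
  cap <- function(x) stringi::stri_trans_totitle(x)
  ym <- !is.na(pd) & n == 7
  out[ym] <- paste(cap(.month_names[as.integer(substr(pd[ym], 6, 7))]),
                   substr(pd[ym], 1, 4))
  full <- !is.na(pd) & n == 10
  out[full] <- sprintf("%s %d, %s",
                       cap(.month_names[as.integer(substr(pd[full], 6, 7))]),
                       as.integer(substr(pd[full], 9, 10)),
                       substr(pd[full], 1, 4))
  yr <- !is.na(pd) & n == 4
  out[yr] <- pd[yr]
  out
}
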