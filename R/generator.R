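#' Synthetic registry generator
#'
#' Generates seeded corpora with the statistical structure of the public
#' ClinicalTrials.gov registry as of early 2012, plus per-trial ground
#' truth, so every pipeline stage is testable without downloading a
#' snapshot. Sponsor names are built by decorating a class keyword with
#' pronounceable nonsense tokens (guaranteeing classifier recoverability);
#' a configurable fraction of names carries no keyword and exercises the
#' agency-class fallback instead. Enrollment anomalies observed in the real
#' registry (zero enrollment, the 99999999 sentinel) are injected at exact
#' configured rates by overriding sampled values.
#'
#' @name synthetic-registry
NULL

#' Default generator configuration
#'
#' Calibrated to the composition of the 2012 registry snapshot: the class
#' mix matches the five-class share of deposits (27.2% edu, 32.1% com,
#' 16.4% gov, 14.5% hos, 8.4% col, 1.4% unclassified); per-class outcome
#' rates, restrained-pool results rates, completion-year weights, FDA /
#' Section-801 marginals, study-type and phase mixes, and enrollment scales
#' mirror the snapshot's published summary counts. The restrained pool is
#' emergent: requirement flags are drawn conditionally independently given
#' class, so all-requirements trials arise at roughly the registry's own
#' prevalence (about half a percent of deposits).
#'
#' @param n_trials corpus size.
#' @return a `registry_config` list; fields are documented inline in the
#'   structure and can be overridden before generation.
#' @export
default_registry_config <- function(n_trials = 20000) {
  classes <- c("edu", "com", "gov", "hos", "col", "unclassified")
  cfg <- list(
    n_trials = as.integer(n_trials),
    classes = classes,
    # five-class share of deposits plus the unclassified residue
    class_mix = c(edu = 0.272, com = 0.321, gov = 0.164, hos = 0.145,
                  col = 0.084, unclassified = 0.014),
    # fraction of com/gov sponsors filed without any class keyword; these
    # are recovered through the agency-class fallback (Industry -> com,
    # NIH / U.S. Fed -> gov). edu/hos/col names always carry a keyword:
    # their fallback (Other) could not recover them.
    keyword_free_frac = 0.15,
    # registry agency class given true class (correspondence-table shares)
    agency_given_class = list(
      edu = c(Industry = 0.0055, NIH = 0, `U.S. Fed` = 0, Other = 0.9945),
      com = c(Industry = 0.9752, NIH = 0, `U.S. Fed` = 0, Other = 0.0248),
      gov = c(Industry = 0.04, NIH = 0.4737, `U.S. Fed` = 0.1017,
              Other = 0.3846),
      hos = c(Industry = 0, NIH = 0, `U.S. Fed` = 0, Other = 1),
      col = c(Industry = 0.016, NIH = 0, `U.S. Fed` = 0, Other = 0.984),
      unclassified = c(Industry = 0, NIH = 0, `U.S. Fed` = 0, Other = 1)),
    # 65937 of 118602 deposits were completed trials
    completed_prob = 0.556,
    status_mix_other = c(`Recruiting` = 0.45, `Active, not recruiting` = 0.25,
                         `Unknown status` = 0.13, `Terminated` = 0.12,
                         `Withdrawn` = 0.05),
    # completion-year weights for completed trials (yearly completed totals;
    # the pre-2001 tail pooled at 2000)
    completion_year_weights = c(
      `2011` = 13945, `2010` = 11732, `2009` = 10588, `2008` = 8869,
      `2007` = 6515, `2006` = 4714, `2005` = 3632, `2004` = 2076,
      `2003` = 1337, `2002` = 840, `2001` = 547, `2000` = 1142),
    # phase mix per class: "none" = no explicit phase ("N/A"). Shapes follow
    # the per-class phase profiles: com peaks at phase 3, gov/col at phase
    # 2, edu lists more phase-4 than phase-3 trials.
    phase_mix = list(
      edu = c(none = 0.45, p1 = 0.12, p2 = 0.16, p3 = 0.09, p4 = 0.13,
              p12 = 0.03, p23 = 0.02),
      com = c(none = 0.35, p1 = 0.12, p2 = 0.15, p3 = 0.20, p4 = 0.13,
              p12 = 0.025, p23 = 0.025),
      gov = c(none = 0.45, p1 = 0.13, p2 = 0.20, p3 = 0.10, p4 = 0.07,
              p12 = 0.03, p23 = 0.02),
      hos = c(none = 0.45, p1 = 0.10, p2 = 0.18, p3 = 0.12, p4 = 0.10,
              p12 = 0.03, p23 = 0.02),
      col = c(none = 0.45, p1 = 0.12, p2 = 0.20, p3 = 0.12, p4 = 0.06,
              p12 = 0.03, p23 = 0.02),
      unclassified = c(none = 0.60, p1 = 0.10, p2 = 0.10, p3 = 0.10,
                       p4 = 0.10, p12 = 0, p23 = 0)),
    # 54544 of 65937 completed trials were interventional
    study_type_mix = c(Interventional = 0.82, Observational = 0.165,
                       `Expanded Access` = 0.01, Other = 0.005),
    # 60% of deposits had a treatment purpose
    primary_purpose_mix = c(Treatment = 0.60, Prevention = 0.12,
                            Diagnostic = 0.08, `Supportive Care` = 0.06,
                            `Basic Science` = 0.05, `Health Services Research` = 0.04,
                            Screening = 0.03, Other = 0.02),
    # 35344/118602 FDA regulated; 25151/35344 of those Section 801
    fda_prob = 0.298,
    s801_given_fda = 0.7116,
    # intervention-type weights for interventional trials (per-class Drug /
    # Procedure / Device shares of interventional trials)
    intervention_mix = list(
      edu = c(Drug = 0.4115, Procedure = 0.1458, Device = 0.0937,
              Behavioral = 0.20, Biological = 0.05, Other = 0.099),
      com = c(Drug = 0.7318, Procedure = 0.021, Device = 0.1264,
              Behavioral = 0.02, Biological = 0.06, Other = 0.0408),
      gov = c(Drug = 0.5399, Procedure = 0.11, Device = 0.0448,
              Behavioral = 0.15, Biological = 0.08, Other = 0.0753),
      hos = c(Drug = 0.3917, Procedure = 0.1998, Device = 0.1131,
              Behavioral = 0.12, Biological = 0.04, Other = 0.1354),
      col = c(Drug = 0.4885, Procedure = 0.1203, Device = 0.0975,
              Behavioral = 0.15, Biological = 0.05, Other = 0.0937),
      unclassified = c(Drug = 0.4, Procedure = 0.15, Device = 0.1,
                       Behavioral = 0.15, Biological = 0.1, Other = 0.1)),
    second_intervention_prob = 0.10,
    # 4675 of 65937 completed trials carried a publication reference
    publication_prob = 0.071,
    extra_references_mean = 0.8,
    # unrestricted per-class results-deposition probability (per-class
    # deposited-results counts over class totals)
    results_prob = c(edu = 0.0143, com = 0.0916, gov = 0.0061, hos = 0.0144,
                     col = 0.0105, unclassified = 0.005),
    # results probability inside the restrained pool (per-class restrained
    # reporting rates)
    results_prob_restrained = c(edu = 0.0979, com = 0.3925, gov = 0.0641,
                                hos = 0.3231, col = 0.0930,
                                unclassified = 0.05),
    # outcome listing rates per class (share with >= 1 outcome; share with
    # > 1 among those)
    outcome_ge1_prob = c(edu = 0.7621, com = 0.7742, gov = 0.3782,
                         hos = 0.7674, col = 0.728, unclassified = 0.70),
    outcome_gt1_given_ge1 = c(edu = 0.3966, com = 0.3525, gov = 0.2972,
                              hos = 0.3610, col = 0.3288,
                              unclassified = 0.30),
    # enrollment: log-normal per class, scaled to per-class average
    # enrollment in the outcome-reporting stratum (the least
    # anomaly-contaminated published scale)
    enrollment_mean = c(edu = 1149, com = 802, gov = 617, hos = 287,
                        col = 1348, unclassified = 500),
    enrollment_sdlog = 1.9,
    enrollment_present_prob = 0.97,
    # anomaly injection: 255/118602 zero-enrollment, 3/118602 sentinel
    zero_enrollment_rate = 0.00215,
    sentinel_enrollment_rate = 2.53e-05,
    sentinel_value = 99999999L,
    arms_weights = c(`1` = 0.20, `2` = 0.45, `3` = 0.20, `4` = 0.10,
                     `5` = 0.05),
    arms_present_prob = 0.80,
    cutoff = as.Date("2011-12-31"))
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param cfg a `registry_config`.
#' @return `cfg` invisibly; errors describe the offending field.
#' @export
validate_registry_config <- function(cfg) {
  check_simplex <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop(sprintf("config error: '%s' must be a probability vector summing to 1",
                   what), call. = FALSE)
    }
  }
  if (cfg$n_trials < 1) stop("config error: n_trials must be positive",
                             call. = FALSE)
  check_simplex(cfg$class_mix, "class_mix")
  check_simplex(cfg$study_type_mix, "study_type_mix")
  check_simplex(cfg$status_mix_other, "status_mix_other")
  for (cl in cfg$classes) {
    check_simplex(cfg$agency_given_class[[cl]],
                  paste0("agency_given_class$", cl))
    check_simplex(cfg$phase_mix[[cl]], paste0("phase_mix$", cl))
    check_simplex(cfg$intervention_mix[[cl]],
                  paste0("intervention_mix$", cl))
  }
  rates <- c(cfg$completed_prob, cfg$fda_prob, cfg$s801_given_fda,
             cfg$publication_prob, cfg$keyword_free_frac,
             cfg$results_prob, cfg$results_prob_restrained,
             cfg$outcome_ge1_prob, cfg$outcome_gt1_given_ge1,
             cfg$zero_enrollment_rate, cfg$sentinel_enrollment_rate,
             cfg$enrollment_present_prob, cfg$arms_present_prob)
  if (any(rates < 0 | rates > 1)) {
    stop("config error: a rate lies outside [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_registry_config`, a validated `registry_config`.
#' @export
read_registry_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_registry_config()
  for (nm in names(raw)) {
    if (nm == "cutoff") {
      cfg$cutoff <- as.Date(raw$cutoff)
    } else if (is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]]))) {
      for (sub in names(raw[[nm]])) cfg[[nm]][[sub]] <- unlist(raw[[nm]][[sub]])
    } else if (!is.null(names(cfg[[nm]])) && length(cfg[[nm]]) > 1) {
      v <- unlist(raw[[nm]])
      cfg[[nm]][names(v)] <- v
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_registry_config(cfg)
  cfg
}

#' @rdname read_registry_config
#' @param cfg a `registry_config`.
#' @export
write_registry_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$cutoff <- format(cfg$cutoff)
  out <- lapply(out, function(x) if (!is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(out, path)
  invisible(path)
}

# pronounceable nonsense tokens for sponsor-name decoration; the syllable
# inventory is chosen so no composition can collide with a dictionary
# keyword at a word boundary
.syllables <- c("vor", "zen", "tak", "mir", "lox", "qua", "fen", "dal",
                "rup", "nim", "bex", "sol", "tri", "gam", "hul", "ost")

random_tokens <- function(n, rng_words = 2) {
  syl <- matrix(sample(.syllables, n * 3, replace = TRUE), ncol = 3)
  word <- paste0(syl[, 1], syl[, 2],
                 ifelse(stats::runif(n) < 0.5, syl[, 3], ""))
  stringi::stri_trans_totitle(word)
}

sample_class <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

# title-case a dictionary keyword for name construction ("inc." -> "Inc.")
keyword_display <- function(kw) {
  stringi::stri_trans_totitle(kw, opts_brkiter = stringi::stri_opts_brkiter(
    type = "word"))
}

#' Generate a synthetic registry corpus
#'
#' Draws `cfg$n_trials` trial records from the configured joint
#' distribution. All randomness comes from one stream keyed by `seed`
#' (restored on exit); fields are drawn for all trials at once in a fixed
#' order, so identical config + seed always yields an identical corpus.
#'
#' @param cfg a `registry_config` (default [default_registry_config()]).
#' @param seed integer seed.
#' @param dict sponsor dictionary used to source class keywords for name
#'   construction.
#' @return a list with `corpus` (tibble, see [trial-corpus]) and `truth`
#'   (tibble: `nct_id`, `true_class`, `keyword_based`, `has_results`,
#'   `outcome_ge1`, plus the five requirement booleans and `restrained`).
#' @export
generate_registry <- function(cfg = default_registry_config(), seed = 1,
                              dict = load_sponsor_dictionary()) {
  validate_registry_config(cfg)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  n <- cfg$n_trials

  nct_id <- sprintf("NCT%08d", seq_len(n))
  true_class <- sample_class(n, cfg$class_mix)

  # --- sponsor name and agency class -------------------------------------
  # keyword-free names only where the fallback can recover the class
  keyword_free <- true_class == "unclassified" |
    (true_class %in% c("com", "gov") &
       stats::runif(n) < cfg$keyword_free_frac)
  agency <- character(n)
  for (cl in cfg$classes) {
    idx <- which(true_class == cl & !keyword_free)
    if (length(idx) > 0) {
      agency[idx] <- sample_class(length(idx), cfg$agency_given_class[[cl]])
    }
  }
  # keyword-free com -> Industry; keyword-free gov -> NIH / U.S. Fed at
  # their relative calibrated shares; keyword-free unclassified -> Other
  kf_com <- which(keyword_free & true_class == "com")
  agency[kf_com] <- "Industry"
  kf_gov <- which(keyword_free & true_class == "gov")
  if (length(kf_gov) > 0) {
    w <- cfg$agency_given_class$gov[c("NIH", "U.S. Fed")]
    agency[kf_gov] <- sample(c("NIH", "U.S. Fed"), length(kf_gov),
                             replace = TRUE, prob = w / sum(w))
  }
  agency[keyword_free & true_class == "unclassified"] <- "Other"

  deco1 <- random_tokens(n)
  deco2 <- random_tokens(n)
  name <- paste(deco1, deco2)  # keyword-free default
  for (cl in sponsor_classes()) {
    idx <- which(true_class == cl & !keyword_free)
    if (length(idx) == 0) next
    kws <- keyword_display(sample(dict$keywords[[cl]], length(idx),
                                  replace = TRUE))
    style <- sample.int(3, length(idx), replace = TRUE)
    name[idx] <- ifelse(style == 1, paste(deco1[idx], kws),
                 ifelse(style == 2, paste(kws, "of", deco1[idx]),
                        paste(deco1[idx], kws, deco2[idx])))
  }

  # --- status and dates ---------------------------------------------------
  completed <- stats::runif(n) < cfg$completed_prob
  status <- character(n)
  status[completed] <- "Completed"
  status[!completed] <- sample_class(sum(!completed), cfg$status_mix_other)

  comp_year <- integer(n)
  w <- cfg$completion_year_weights
  comp_year[completed] <- as.integer(sample(names(w), sum(completed),
                                            replace = TRUE, prob = w))
  comp_month <- sample.int(12, n, replace = TRUE)
  completion_date <- sprintf("%d-%02d", comp_year, comp_month)
  # non-completed trials: anticipated completion after the snapshot, or none
  fut <- which(!completed)
  has_future <- stats::runif(length(fut)) < 0.7
  completion_date[fut[!has_future]] <- NA_character_
  if (any(has_future)) {
    fy <- sample(2012:2015, sum(has_future), replace = TRUE)
    completion_date[fut[has_future]] <-
      sprintf("%d-%02d", fy, comp_month[fut[has_future]])
  }
  # start precedes completion by 0-4 years
  lag <- sample(0:4, n, replace = TRUE,
                prob = c(0.15, 0.35, 0.25, 0.15, 0.10))
  start_year <- ifelse(is.na(completion_date),
                       sample(2005:2011, n, replace = TRUE),
                       as.integer(substr(completion_date, 1, 4)) - lag)
  start_date <- sprintf("%d-%02d", start_year,
                        sample.int(12, n, replace = TRUE))
  # granularity variation: a few year-only and day-resolved dates
  gran <- stats::runif(n)
  year_only <- gran < 0.03
  start_date[year_only] <- substr(start_date[year_only], 1, 4)
  completion_date[year_only & !is.na(completion_date)] <-
    substr(completion_date[year_only & !is.na(completion_date)], 1, 4)
  day_res <- gran > 0.98
  start_date[day_res] <- paste0(start_date[day_res], sprintf(
    "-%02d", sample.int(28, sum(day_res), replace = TRUE)))
  start_date[stats::runif(n) < 0.02] <- NA_character_

  # --- design fields -------------------------------------------------------
  phase_token <- character(n)
  for (cl in cfg$classes) {
    idx <- which(true_class == cl)
    phase_token[idx] <- sample_class(length(idx), cfg$phase_mix[[cl]])
  }
  phase_raw <- unname(c(none = "N/A", p1 = "Phase 1", p2 = "Phase 2",
                        p3 = "Phase 3", p4 = "Phase 4",
                        p12 = "Phase 1/Phase 2",
                        p23 = "Phase 2/Phase 3")[phase_token])
  study_type <- sample_class(n, cfg$study_type_mix)
  primary_purpose <- ifelse(study_type == "Interventional",
                            sample_class(n, cfg$primary_purpose_mix),
                            NA_character_)

  interventional <- study_type == "Interventional"
  intervention_types <- vector("list", n)
  intervention_types[!interventional] <- list(character(0))
  for (cl in cfg$classes) {
    idx <- which(true_class == cl & interventional)
    if (length(idx) == 0) next
    first <- sample_class(length(idx), cfg$intervention_mix[[cl]])
    second <- sample_class(length(idx), cfg$intervention_mix[[cl]])
    two <- stats::runif(length(idx)) < cfg$second_intervention_prob &
      second != first
    intervention_types[idx] <- purrr::map2(first, seq_along(idx), function(f, i)
      if (two[[i]]) c(f, second[[i]]) else f)
  }

  fda <- stats::runif(n) < cfg$fda_prob
  s801 <- fda & stats::runif(n) < cfg$s801_given_fda
  # oversight flags absent (unknown) on a small fraction of records
  fda_known <- stats::runif(n) < 0.95
  is_fda_regulated <- ifelse(fda_known, fda, NA)
  is_section_801 <- ifelse(fda_known, s801, NA)

  has_pub <- stats::runif(n) < cfg$publication_prob
  n_references <- ifelse(has_pub,
                         1L + stats::rpois(n, cfg$extra_references_mean), 0L)

  # --- emergent restrained pool, then reporting indicators ----------------
  phase_2_4 <- phase_token %in% c("p2", "p3", "p4", "p12", "p23")
  completed_by_cutoff <- completed  # completion dates above are all <= cutoff
  restrained <- completed_by_cutoff & fda & s801 & phase_2_4 & has_pub &
    interventional

  p_res <- unname(ifelse(restrained,
                         cfg$results_prob_restrained[true_class],
                         cfg$results_prob[true_class]))
  has_results <- stats::runif(n) < p_res

  out_ge1 <- unname(stats::runif(n) < cfg$outcome_ge1_prob[true_class])
  out_gt1 <- out_ge1 &
    unname(stats::runif(n) < cfg$outcome_gt1_given_ge1[true_class])
  n_primary <- ifelse(out_ge1, 1L, 0L)
  n_secondary <- ifelse(out_gt1, 1L + stats::rpois(n, 1), 0L)

  # --- enrollment and arms -------------------------------------------------
  mu <- log(cfg$enrollment_mean[true_class]) - cfg$enrollment_sdlog^2 / 2
  enrollment <- as.integer(pmax(1, round(stats::rlnorm(
    n, meanlog = mu, sdlog = cfg$enrollment_sdlog))))
  enrollment[stats::runif(n) >= cfg$enrollment_present_prob] <- NA_integer_
  # anomaly injection overrides sampled values so the rates are exact params
  u_anom <- stats::runif(n)
  enrollment[u_anom < cfg$zero_enrollment_rate] <- 0L
  enrollment[u_anom >= cfg$zero_enrollment_rate &
               u_anom < cfg$zero_enrollment_rate +
               cfg$sentinel_enrollment_rate] <- cfg$sentinel_value
  enrollment_type <- ifelse(is.na(enrollment), NA_character_,
                            ifelse(completed,
                                   ifelse(stats::runif(n) < 0.85, "Actual",
                                          "Anticipated"),
                                   ifelse(stats::runif(n) < 0.9, "Anticipated",
                                          "Actual")))
  number_of_arms <- ifelse(stats::runif(n) < cfg$arms_present_prob,
                           as.integer(sample_class(n, cfg$arms_weights)),
                           NA_integer_)

  corpus <- tibble::tibble(
    nct_id = nct_id, lead_sponsor_name = name, agency_class = agency,
    overall_status = status, start_date = start_date,
    completion_date = completion_date, phase_raw = phase_raw,
    study_type = study_type, intervention_types = intervention_types,
    primary_purpose = primary_purpose, is_fda_regulated = is_fda_regulated,
    is_section_801 = is_section_801, has_results = has_results,
    n_primary_outcomes = n_primary, n_secondary_outcomes = n_secondary,
    n_references = n_references, enrollment = enrollment,
    enrollment_type = enrollment_type, number_of_arms = number_of_arms)

  truth <- tibble::tibble(
    nct_id = nct_id, true_class = true_class, keyword_based = !keyword_free,
    has_results = has_results, outcome_ge1 = out_ge1,
    completed_by_cutoff = completed_by_cutoff,
    fda_regulated = fda, section_801 = s801, phase_2_to_4 = phase_2_4,
    has_publication = has_pub, interventional = interventional,
    restrained = restrained)

  list(corpus = corpus, truth = truth)
}

#' Write a corpus as one registry-XML file per trial
#'
#' Serialises each record in the `clinical_study` dialect that
#' [read_registry_xml()] parses; absent fields produce no element. File
#' names are `<nct_id>.xml`.
#'
#' @param corpus a corpus tibble.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_corpus_xml <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(corpus$nct_id, ".xml"))
  # oversight flags generated together: absent is all-or-nothing per record
  for (i in seq_len(nrow(corpus))) {
    doc <- xml2::xml_new_root("clinical_study")
    id <- xml2::xml_add_child(doc, "id_info")
    xml2::xml_add_child(id, "nct_id", corpus$nct_id[[i]])
    sp <- xml2::xml_add_child(doc, "sponsors")
    lead <- xml2::xml_add_child(sp, "lead_sponsor")
    xml2::xml_add_child(lead, "agency", corpus$lead_sponsor_name[[i]])
    xml2::xml_add_child(lead, "agency_class", corpus$agency_class[[i]])
    add_opt <- function(tag, value) {
      if (!is.na(value)) xml2::xml_add_child(doc, tag, as.character(value))
    }
    add_opt("overall_status", corpus$overall_status[[i]])
    add_opt("start_date", format_partial_date(corpus$start_date[[i]]))
    add_opt("completion_date",
            format_partial_date(corpus$completion_date[[i]]))
    add_opt("phase", corpus$phase_raw[[i]])
    add_opt("study_type", corpus$study_type[[i]])
    if (!is.na(corpus$primary_purpose[[i]])) {
      sd <- xml2::xml_add_child(doc, "study_design_info")
      xml2::xml_add_child(sd, "primary_purpose", corpus$primary_purpose[[i]])
    }
    if (!is.na(corpus$is_fda_regulated[[i]]) ||
        !is.na(corpus$is_section_801[[i]])) {
      ov <- xml2::xml_add_child(doc, "oversight_info")
      if (!is.na(corpus$is_fda_regulated[[i]])) {
        xml2::xml_add_child(ov, "is_fda_regulated",
                            if (corpus$is_fda_regulated[[i]]) "Yes" else "No")
      }
      if (!is.na(corpus$is_section_801[[i]])) {
        xml2::xml_add_child(ov, "is_section_801",
                            if (corpus$is_section_801[[i]]) "Yes" else "No")
      }
    }
    for (ty in corpus$intervention_types[[i]]) {
      iv <- xml2::xml_add_child(doc, "intervention")
      xml2::xml_add_child(iv, "intervention_type", ty)
    }
    for (k in seq_len(corpus$n_primary_outcomes[[i]])) {
      po <- xml2::xml_add_child(doc, "primary_outcome")
      xml2::xml_add_child(po, "measure", sprintf("Primary measure %d", k))
    }
    for (k in seq_len(corpus$n_secondary_outcomes[[i]])) {
      so <- xml2::xml_add_child(doc, "secondary_outcome")
      xml2::xml_add_child(so, "measure", sprintf("Secondary measure %d", k))
    }
    for (k in seq_len(corpus$n_references[[i]])) {
      rf <- xml2::xml_add_child(doc, "reference")
      xml2::xml_add_child(rf, "citation", sprintf("Reference %d", k))
    }
    if (!is.na(corpus$enrollment[[i]])) {
      enr <- xml2::xml_add_child(doc, "enrollment",
                                 as.character(corpus$enrollment[[i]]))
      if (!is.na(corpus$enrollment_type[[i]])) {
        xml2::xml_set_attr(enr, "type", corpus$enrollment_type[[i]])
      }
    }
    add_opt("number_of_arms", corpus$number_of_arms[[i]])
    if (corpus$has_results[[i]]) {
      res <- xml2::xml_add_child(doc, "clinical_results")
      xml2::xml_add_child(res, "participant_flow")
    }
    xml2::write_xml(doc, paths[[i]])
  }
  invisible(paths)
}
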