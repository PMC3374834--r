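# Construct trial records in code: a one-row corpus with sensible defaults,
# overridable per field. All fixtures are built at test time.
make_trial <- function(nct_id = "NCT00000001",
                       lead_sponsor_name = "Vorzen Taklox",
                       agency_class = "Other",
                       overall_status = "Completed",
                       start_date = "2006-03",
                       completion_date = "2008-06",
                       phase_raw = "Phase 3",
                       study_type = "Interventional",
                       intervention_types = list("Drug"),
                       primary_purpose = "Treatment",
                       is_fda_regulated = TRUE,
                       is_section_801 = TRUE,
                       has_results = FALSE,
                       n_primary_outcomes = 1L,
                       n_secondary_outcomes = 0L,
                       n_references = 1L,
                       enrollment = 100L,
                       enrollment_type = "Actual",
                       number_of_arms = 2L) {
  tibble::tibble(
    nct_id = nct_id, lead_sponsor_name = lead_sponsor_name,
    agency_class = agency_class, overall_status = overall_status,
    start_date = start_date, completion_date = completion_date,
    phase_raw = phase_raw, study_type = study_type,
    intervention_types = intervention_types,
    primary_purpose = primary_purpose,
    is_fda_regulated = is_fda_regulated, is_section_801 = is_section_801,
    has_results = has_results, n_primary_outcomes = n_primary_outcomes,
    n_secondary_outcomes = n_secondary_outcomes,
    n_references = n_references, enrollment = enrollment,
    enrollment_type = enrollment_type, number_of_arms = number_of_arms)
}

make_corpus <- function(...) {
  trials <- list(...)
  corp <- dplyr::bind_rows(trials)
  if (!"sponsor_class" %in% names(corp)) corp
  else corp
}

# registry XML text for a minimal record, for parser tests
minimal_xml <- function(nct_id = "NCT00000001", extra = "") {
  sprintf(
    '<clinical_study><id_info><nct_id>%s</nct_id></id_info>%s</clinical_study>',
    nct_id, extra)
}

write_xml_fixture <- function(dir, filename, content) {
  path <- file.path(dir, filename)
  writeLines(content, path, useBytes = TRUE)
  path
}
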