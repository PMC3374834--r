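test_that("percent rounds half-up and flags empty denominators", {
  expect_equal(percent(168, 428), 39.25)
  expect_equal(percent(75, 135), 55.56)
  expect_equal(percent(220, 634, 1), 34.7)
  expect_equal(percent(0, 100), 0)
  expect_true(is.na(percent(0, 0)))
  # half-up at the boundary, where round-half-even would differ
  expect_equal(percent(1, 8, 1), 12.5)
  expect_equal(percent(1, 800, 2), 0.13)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("yearly requirement table counts by bucket and requirement", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", completion_date = "2008-03", has_results = TRUE),
    make_trial("NCT00000002", completion_date = "2008-09"),
    make_trial("NCT00000003", completion_date = "1998-01", has_results = TRUE,
               n_references = 0L),
    make_trial("NCT00000004", overall_status = "Recruiting",
               completion_date = NA_character_))
  tab <- yearly_requirement_table(corp, compute_flags(corp))
  overall <- tab[tab$requirement == "overall", ]
  expect_equal(overall$total[overall$year_bucket == "2008"], 2)
  expect_equal(overall$with_results[overall$year_bucket == "2008"], 1)
  expect_equal(overall$pct[overall$year_bucket == "2008"], 50)
  expect_equal(overall$total[overall$year_bucket == "2000 and before"], 1)
  expect_equal(overall$total[overall$year_bucket == "total"], 3)
  # the no-publication trial leaves the all-requirements column
  allreq <- tab[tab$requirement == "all_requirements", ]
  expect_equal(allreq$total[allreq$year_bucket == "total"], 2)
  # empty buckets report n/a percent, zero counts
  expect_true(is.na(overall$pct[overall$year_bucket == "2005"]))
})

test_that("uniform results presence yields 100 percent everywhere", {
  gen <- generate_registry(default_registry_config(500), seed = 21)
  corp <- gen$corpus
  corp$has_results <- TRUE
  tab <- yearly_requirement_table(corp, compute_flags(corp))
  filled <- tab[tab$total > 0, ]
  expect_true(all(filled$pct == 100))
  # and a corpus with no completed trials yields empty totals
  never <- corp
  never$overall_status <- "Recruiting"
  tab0 <- yearly_requirement_table(never, compute_flags(never))
  expect_true(all(tab0$total == 0))
  expect_true(all(is.na(tab0$pct)))
})

test_that("yearly deposition rate is recovered within sampling bounds", {
  # completed 2008 trials deposit results with p = 0.15 by construction
  cfg <- default_registry_config(8000)
  gen <- generate_registry(cfg, seed = 9)
  corp <- gen$corpus
  yr <- partial_date_year(corp$completion_date)
  pick <- corp$overall_status == "Completed" & !is.na(yr) & yr == 2008
  set.seed(99)
  corp$has_results[pick] <- runif(sum(pick)) < 0.15
  tab <- yearly_requirement_table(corp, compute_flags(corp))
  cell <- tab[tab$requirement == "overall" & tab$year_bucket == "2008", ]
  expect_gt(cell$total, 300)  # enough completions to make the bound sharp
  expect_lt(abs(cell$pct - 15), 3)
})

test_that("restrained class table reports per-class deposition", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", has_results = TRUE),
    make_trial("NCT00000002"),
    make_trial("NCT00000003", n_references = 0L))
  corp$sponsor_class <- c("com", "com", "hos")
  flags <- compute_flags(corp)
  expect_warning(tab <- class_restrained_table(corp, flags),
                 "hos")  # hos trial fails the cascade -> class omitted
  expect_equal(tab$sponsor_class, "com")
  expect_equal(tab$with_results, 1L)
  expect_equal(tab$total, 2L)
  expect_equal(tab$pct, 50)
  # a one-trial class with results reports 100
  solo <- make_trial("NCT00000009", has_results = TRUE)
  solo$sponsor_class <- "gov"
  suppressWarnings(tab1 <- class_restrained_table(solo, compute_flags(solo)))
  expect_equal(tab1$pct, 100)
})

test_that("outcome counting distinguishes at-least-one from more-than-one", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", n_primary_outcomes = 1L,
               n_secondary_outcomes = 0L),
    make_trial("NCT00000002", n_primary_outcomes = 1L,
               n_secondary_outcomes = 1L),
    make_trial("NCT00000003", n_primary_outcomes = 0L,
               n_secondary_outcomes = 0L))
  corp$sponsor_class <- "edu"
  tab <- outcome_table(corp)
  expect_equal(tab$n_at_least_one, 2L)
  expect_equal(tab$n_more_than_one, 1L)
  expect_equal(tab$pct_at_least_one, percent(2, 3))
  expect_equal(tab$pct_more_than_one, percent(1, 3))
})

test_that("intervention table handles multi-type trials and empty cells", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", intervention_types = list(c("Drug", "Device")),
               has_results = TRUE),
    make_trial("NCT00000002", intervention_types = list("Drug")),
    make_trial("NCT00000003", study_type = "Observational",
               intervention_types = list(character(0))))
  corp$sponsor_class <- "com"
  tab <- intervention_table(corp)
  drug <- tab[tab$intervention == "Drug", ]
  dev <- tab[tab$intervention == "Device", ]
  proc <- tab[tab$intervention == "Procedure", ]
  expect_equal(drug$n_trials, 2L)       # the two-type trial counts in both
  expect_equal(dev$n_trials, 1L)
  expect_equal(drug$share_pct, 100)     # share of the 2 interventional trials
  expect_equal(drug$efficiency_pct, 50)
  expect_equal(dev$efficiency_pct, 100)
  expect_true(is.na(proc$efficiency_pct))  # no procedure trials -> n/a
  # share denominator switch: of all class trials instead
  tab_all <- intervention_table(corp, share_denominator = "all")
  expect_equal(tab_all$share_pct[tab_all$intervention == "Drug"],
               percent(2, 3))
})

test_that("enrollment summaries stratify and keep anomalies visible", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", enrollment = 7L, has_results = TRUE),
    make_trial("NCT00000002", enrollment = 99999999L,
               study_type = "Observational", n_primary_outcomes = 0L),
    make_trial("NCT00000003", enrollment = NA_integer_),
    make_trial("NCT00000004", overall_status = "Recruiting",
               enrollment = 50L))
  corp$sponsor_class <- "gov"
  tab <- enrollment_table(corp)
  all_row <- tab[tab$stratum == "all", ]
  expect_equal(all_row$n_trials, 2L)  # NA enrollment and Recruiting excluded
  expect_equal(all_row$max_enrollment, 99999999)
  expect_equal(all_row$total_participants, 100000006)
  expect_equal(all_row$average_enrollment, 50000003)
  # the sentinel trial has no results and no outcome: narrower strata drop it
  res_row <- tab[tab$stratum == "with_results", ]
  expect_equal(res_row$n_trials, 1L)
  expect_equal(res_row$max_enrollment, 7)
  expect_equal(res_row$average_enrollment, 7)
  expect_equal(res_row$total_participants, 7)
})

test_that("yearly activity counts starts and completions independently", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", start_date = "2009-01",
               completion_date = "2011-05"),
    make_trial("NCT00000002", start_date = "2009-11",
               completion_date = "2011-02"),
    make_trial("NCT00000003", start_date = NA_character_,
               completion_date = "2011-07"))
  act <- yearly_activity(corp)
  expect_equal(act$n_started[act$year == 2009], 2L)
  expect_equal(act$n_completed[act$year == 2011], 3L)
  # 2011-style phenomenon: completions can exceed starts within a year
  expect_gt(act$n_completed[act$year == 2011],
            act$n_started[act$year == 2011])
})

test_that("phase distribution counts multi-phase trials once per phase", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", phase_raw = "Phase 2/Phase 3"),
    make_trial("NCT00000002", phase_raw = "N/A"),
    make_trial("NCT00000003", phase_raw = "Phase 2"))
  corp$sponsor_class <- "com"
  tab <- phase_distribution(corp)
  expect_equal(tab$n_trials[tab$phase == 2], 2L)
  expect_equal(tab$n_trials[tab$phase == 3], 1L)
  expect_equal(tab$n_trials[tab$phase == 1], 0L)
  # all-N/A corpus: every cell zero
  na_corp <- corp
  na_corp$phase_raw <- "N/A"
  expect_true(all(phase_distribution(na_corp)$n_trials == 0))
})

test_that("table percent columns always recompute from their counts", {
  gen <- generate_registry(default_registry_config(4000), seed = 33)
  corp <- add_sponsor_class(gen$corpus)
  flags <- compute_flags(corp)
  yearly <- yearly_requirement_table(corp, flags)
  expect_equal(yearly$pct, percent(yearly$with_results, yearly$total))
  out <- outcome_table(corp)
  expect_equal(out$pct_at_least_one, percent(out$n_at_least_one,
                                             out$class_total))
  # all-requirements totals never exceed any single-requirement total
  wide <- as.data.frame(split(yearly$total, yearly$requirement))
  for (rq in setdiff(unique(yearly$requirement), "all_requirements")) {
    expect_true(all(wide$all_requirements <= wide[[rq]]))
  }
})
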