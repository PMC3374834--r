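test_that("cross-product odds ratio matches hand-computed values", {
  expect_equal(odds_ratio(contingency_2x2(25, 25, 25, 25)), 1)
  expect_equal(odds_ratio(contingency_2x2(10, 5, 2, 8)), 8)  # (10*8)/(5*2)
})

test_that("zero cells are explicit errors unless corrected", {
  expect_error(odds_ratio(contingency_2x2(5, 0, 2, 8)), "off-diagonal")
  expect_error(odds_ratio(contingency_2x2(5, 1, 0, 8)), "off-diagonal")
  corrected <- odds_ratio(contingency_2x2(5, 0, 2, 8), correction = "haldane")
  expect_equal(corrected, (5.5 * 8.5) / (0.5 * 2.5))
  expect_error(contingency_2x2(0, 0, 0, 0), "empty")
})

test_that("algebraic identities hold over random tables", {
  set.seed(202)
  for (i in 1:200) {
    cells <- sample(1:400, 4, replace = TRUE)
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    or <- odds_ratio(tab)
    # row swap inverts
    expect_equal(odds_ratio(contingency_2x2(cells[3], cells[4], cells[1],
                                            cells[2])), 1 / or)
    # transposition (swap X and Y) leaves the OR unchanged
    expect_equal(odds_ratio(contingency_2x2(cells[1], cells[3], cells[2],
                                            cells[4])), or)
    # scaling all cells by a positive integer leaves the OR unchanged
    expect_equal(odds_ratio(contingency_2x2(3 * cells[1], 3 * cells[2],
                                            3 * cells[3], 3 * cells[4])), or)
    # count form equals the joint-probability form
    p <- joint_probabilities(tab)
    expect_equal(or, (p[["p11"]] * p[["p00"]]) / (p[["p10"]] * p[["p01"]]))
  }
})

test_that("confidence bounds bracket the estimate and shrink with n", {
  tab <- contingency_2x2(40, 20, 25, 35)
  ci <- odds_ratio_ci(tab)
  expect_lte(ci$ci_low, ci$or)
  expect_gte(ci$ci_high, ci$or)
  expect_gt(ci$ci_low, 0)
  big <- contingency_2x2(4000, 2000, 2500, 3500)
  ci_big <- odds_ratio_ci(big)
  expect_lt(ci_big$ci_high - ci_big$ci_low, ci$ci_high - ci$ci_low)
})

test_that("t-based and normal-based intervals converge at large n", {
  tab <- contingency_2x2(2500, 2500, 2500, 2500)  # n = 10,000
  ci_t <- odds_ratio_ci(tab, method = "t")
  ci_z <- odds_ratio_ci(tab, method = "normal")
  w_t <- log(ci_t$ci_high) - log(ci_t$ci_low)
  w_z <- log(ci_z$ci_high) - log(ci_z$ci_low)
  expect_lt(abs(w_t - w_z) / w_z, 0.001)
  expect_gt(w_t, w_z)  # t is always the (slightly) wider of the two
})

test_that("class contingency tables count the corpus correctly", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", has_results = TRUE),
    make_trial("NCT00000002", has_results = TRUE),
    make_trial("NCT00000003"),
    make_trial("NCT00000004"))
  corp$sponsor_class <- c("com", "com", "com", "edu")
  tab <- build_contingency(corp, "com", "results")
  expect_equal(tab$n11, 2L)
  expect_equal(tab$n10, 1L)
  expect_equal(tab$n01, 0L)
  expect_equal(tab$n00, 1L)
})

test_that("excluded classes vanish from both margins", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", has_results = TRUE),
    make_trial("NCT00000002"),
    make_trial("NCT00000003", has_results = TRUE),
    make_trial("NCT00000004"))
  corp$sponsor_class <- c("com", "edu", "col", "col")
  tab <- build_contingency(corp, "com", "results", exclude = c("col"))
  expect_equal(tab$n11 + tab$n10 + tab$n01 + tab$n00, 2L)
  expect_error(build_contingency(corp, "col", "results"),
               "exclusion set")
})

test_that("degenerate pools fail loudly before any OR is computed", {
  corp <- dplyr::bind_rows(
    make_trial("NCT00000001", has_results = TRUE),
    make_trial("NCT00000002"))
  corp$sponsor_class <- "com"
  expect_error(build_contingency(corp, "com", "results"), "zero margin")
  # empty restrained pool
  corp2 <- corp
  corp2$n_references <- 0L
  corp2$sponsor_class <- c("com", "edu")
  flags <- compute_flags(corp2)
  expect_error(build_contingency(corp2, "com", "results", flags = flags,
                                 restrained = TRUE), "empty restrained pool")
})

test_that("OR estimates converge to the generating odds as n grows", {
  # com results-odds are ~4x the rest by calibration at the configured
  # rates; the absolute log-error should shrink in expectation with n
  errs <- vapply(c(500, 5000, 50000), function(n) {
    cfg <- default_registry_config(n)
    # flatten per-class rates to a clean 4x odds contrast for com
    cfg$results_prob[] <- 0.05
    cfg$results_prob["com"] <- 0.174  # odds 0.2105 ~= 4 x 0.0526
    cfg$results_prob_restrained <- cfg$results_prob
    mean(vapply(1:8, function(s) {
      gen <- generate_registry(cfg, seed = 1000 + s)
      corp <- gen$corpus
      corp$sponsor_class <- gen$truth$true_class
      tab <- build_contingency(corp, "com", "results")
      abs(log(odds_ratio(tab)) - log(4))
    }, numeric(1)))
  }, numeric(1))
  expect_true(errs[2] < errs[1] && errs[3] < errs[2])
  expect_lt(errs[3], 0.1)
})

test_that("null corpora produce CIs covering 1 at the nominal rate", {
  cfg <- default_registry_config(2500)
  cfg$results_prob[] <- 0.08
  cfg$results_prob_restrained[] <- 0.08
  covered <- vapply(1:60, function(s) {
    gen <- generate_registry(cfg, seed = 3000 + s)
    corp <- gen$corpus
    corp$sponsor_class <- gen$truth$true_class
    ci <- odds_ratio_ci(build_contingency(corp, "com", "results"))
    ci$ci_low <= 1 && 1 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
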