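dict <- load_sponsor_dictionary()

test_that("name normalisation case-folds, collapses whitespace, keeps diacritics", {
  expect_equal(normalize_name("  PFIZER  Inc."), "pfizer inc.")
  expect_equal(normalize_name("Università di Bologna"), "università di bologna")
  expect_equal(normalize_name(""), "")
  # idempotence over random strings
  set.seed(101)
  rand <- vapply(1:50, function(i) {
    paste(sample(c(LETTERS, letters, " ", ".", "é", "ô", "\t"), 20,
                 replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(normalize_name(normalize_name(rand)), normalize_name(rand))
})

test_that("hospital outranks university and multilingual keywords match", {
  expect_equal(classify_sponsor("University Hospital Basel", "Other", dict),
               "hos")
  expect_equal(classify_sponsor("Hôpitaux de Paris", "Other", dict), "hos")
  expect_equal(classify_sponsor("Università di Bologna", "Other", dict), "edu")
  expect_equal(classify_sponsor("Klinikum rechts der Isar", "Other", dict),
               "hos")
  expect_equal(classify_sponsor("Acme Corp.", "Industry", dict), "com")
  expect_equal(classify_sponsor("Acme Corp", "Industry", dict), "com")
})

test_that("keyword matching respects word boundaries", {
  # "Include" must not match the corporate suffix "inc."
  expect_equal(classify_sponsor("Include", "Other", dict), "unclassified")
  expect_equal(classify_sponsor("Zinc Works", "Other", dict), "unclassified")
  expect_equal(classify_sponsor("Principality Trust", "Other", dict),
               "unclassified")
})

test_that("agency-class fallback covers keyword-free names", {
  expect_equal(classify_sponsor("Xyzzy Foundation", "NIH", dict), "gov")
  expect_equal(classify_sponsor("Xyzzy Foundation", "U.S. Fed", dict), "gov")
  expect_equal(classify_sponsor("Xyzzy Foundation", "Industry", dict), "com")
  expect_equal(classify_sponsor("Xyzzy Foundation", "Other", dict),
               "unclassified")
})

test_that("classification is total, deterministic, and priority-respecting", {
  gen <- generate_registry(default_registry_config(2000), seed = 5)
  a1 <- classify_corpus(gen$corpus, dict)
  a2 <- classify_corpus(gen$corpus, dict)
  expect_equal(nrow(a1$assignments), nrow(gen$corpus))
  expect_false(anyNA(a1$assignments$sponsor_class))
  expect_identical(a1$assignments, a2$assignments)
  # summary shares: counts over the full corpus, unclassified included
  expect_equal(sum(a1$summary$n), nrow(gen$corpus))
  # names combining a hospital and a university keyword always land in hos
  combos <- paste("Vorzen University Hospital", c("", "of Mirqua"))
  expect_true(all(classify_sponsor(combos, "Other", dict) == "hos"))
})

test_that("every keyworded sponsor name recovers its generating class", {
  gen <- generate_registry(default_registry_config(4000), seed = 8)
  cls <- classify_sponsor(gen$corpus$lead_sponsor_name,
                          gen$corpus$agency_class, dict)
  expect_equal(cls, gen$truth$true_class)
})

test_that("class mix is recovered within binomial bounds at n = 10,000", {
  cfg <- default_registry_config(10000)
  gen <- generate_registry(cfg, seed = 17)
  got <- classify_corpus(gen$corpus, dict)$summary
  shares <- got$share_pct[match(names(cfg$class_mix), got$sponsor_class)]
  # 2-point band: > 4 sigma for every class share at n = 10,000
  expect_true(all(abs(shares - 100 * cfg$class_mix) < 2))
})

test_that("diacritic folding is off by default and available by switch", {
  expect_equal(classify_sponsor("Hopitaux de Paris", "Other", dict),
               "unclassified")
  folded <- load_sponsor_dictionary(fold_diacritics = TRUE)
  expect_equal(classify_sponsor("Hopitaux de Paris", "Other", folded), "hos")
})

test_that("dictionary files are validated on load", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("priority: [a, b]", "fallback:", "  Industry: com",
               "  NIH: gov", "  'U.S. Fed': gov", "  Other: unclassified",
               "classes:", "  a:", "    keywords: [x]"), path)
  expect_error(load_sponsor_dictionary(path), "exactly the classes")
  writeLines(c("priority: [a]", "classes:", "  a:", "    keywords: [x]"),
             path)
  expect_error(load_sponsor_dictionary(path), "fallback")
})
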