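# The synthetic-data generator: determinism, ground-truth invariants and
# planted-effect calibration.

test_that("formula libraries are deterministic and pass the assignment rules", {
  a <- sample_formula_library(100, c(85, 500), seed = 7)
  b <- sample_formula_library(100, c(85, 500), seed = 7)
  expect_identical(a, b)
  expect_identical(nrow(a), 100L)
  expect_true(all(a$mass >= 85 & a$mass <= 500))
  # every generated formula passes the independently rewritten rules oracle
  pass <- mapply(oracle_rules_pass, a$c, a$h, a$n, a$o, a$p, a$s)
  expect_true(all(pass))
})

test_that("a range admitting only water yields H2O", {
  cfg <- formula_config(bounds = c(c = 0, n = 0, p = 0, s = 0), min_c = 0)
  lib <- sample_formula_library(1, c(18, 19), seed = 1, config = cfg)
  expect_identical(lib$formula, "H2O")
  expect_error(sample_formula_library(1, c(18.5, 18.6), seed = 1, config = cfg),
               "no valid CHNOPS formula")
})

test_that("zero noise and zero effects give identical sample intensities", {
  design <- synthetic_design(groups = c("a", "b"), n_per_group = 3,
                             n_blanks = 1, seed = 1)
  lib <- sample_formula_library(20, c(85, 400), seed = 2)
  sim <- simulate_feature_table(design, lib, noise_sdlog = 0,
                                mass_error_ppm_sd = 0, blank_fraction = 0,
                                background_fraction = 0,
                                internal_standards = FALSE, seed = 3)
  nb <- design$sample_id[!design$is_blank]
  inten <- sim$table$intensities[, nb]
  expect_true(all(apply(inten, 1, function(r) diff(range(r)) == 0)))
})

test_that("glutamine is emitted at its exact [M-H]- m/z when error is zero", {
  design <- synthetic_design(groups = c("a", "b"), n_per_group = 2,
                             n_blanks = 0, seed = 1)
  lib <- sample_formula_library(5, c(85, 400), seed = 2)
  lib[1, c("c", "h", "n", "o", "p", "s")] <- c(5, 10, 2, 3, 0, 0)
  lib$formula[1] <- "C5H10N2O3"
  lib$mass[1] <- monoisotopic_mass("C5H10N2O3")
  sim <- simulate_feature_table(design, lib, mass_error_ppm_sd = 0,
                                internal_standards = FALSE, seed = 3)
  expect_equal(sim$table$features$mz[1], 146.0691422 - 1.007276466,
               tolerance = 1e-6)
  expect_equal(neutral_mass_from_mz(sim$table$features$mz[1]), lib$mass[1],
               tolerance = 1e-9)
})

test_that("recorded m/z is exactly reconstructible from the stored truth", {
  design <- synthetic_design(seed = 4)
  lib <- sample_formula_library(60, c(85, 700), seed = 5)
  sim <- simulate_feature_table(design, lib, seed = 6)
  rebuilt <- (sim$truth$true_mass - 1.007276466) *
    (1 + sim$truth$mz_error_ppm * 1e-6)
  expect_identical(sim$table$features$mz, rebuilt)
  expect_true(all(abs(sim$truth$mz_error_ppm) <= 3 * 0.5 + 1e-12))
  # same seed, byte-identical output
  sim2 <- simulate_feature_table(design, lib, seed = 6)
  expect_identical(sim, sim2)
})

test_that("retention times respect the scan windows", {
  design <- synthetic_design(seed = 1)
  lib <- sample_formula_library(300, c(85, 1000), seed = 2)
  sim <- simulate_feature_table(design, lib, seed = 3)
  mz <- sim$table$features$mz
  rt <- sim$table$features$rt_min
  expect_true(all(rt[mz < 110] < 9))
  expect_true(all(rt[mz > 800] > 9))
})

test_that("a planted 2-fold effect is realised to within 0.1 log2 units", {
  design <- synthetic_design(groups = c("pasture", "grove"), n_per_group = 4,
                             n_blanks = 0, seed = 10)
  lib <- sample_formula_library(300, c(85, 500), seed = 11)
  sim <- simulate_feature_table(design, lib, effects = list(grove = 1),
                                internal_standards = FALSE, seed = 12)
  ga <- design$sample_id[design$group == "grove"]
  gr <- design$sample_id[design$group == "pasture"]
  lfc <- log2(rowMeans(sim$table$intensities[, ga]) /
                rowMeans(sim$table$intensities[, gr]))
  expect_lt(abs(mean(lfc) - 1), 0.1)
})

test_that("internal standards hit their target CV", {
  # Monte-Carlo over seeds: a 5% target CV estimated from 24 samples stays
  # within a [2, 9]% band
  cvs <- vapply(1:100, function(s) {
    design <- synthetic_design(seed = s)
    lib <- sample_formula_library(10, c(85, 400), seed = 1)
    sim <- simulate_feature_table(design, lib, is_cv_pct = 5, seed = s)
    internal_standard_cv(sim$table, "IS_phenylalanine", sim$design)$cv_pct
  }, numeric(1))
  expect_true(all(cvs >= 2 & cvs <= 9))
})

test_that("the stoichiometric cohort plants a phosphorus contrast", {
  d <- simulate_stoich_cohort(200, seed = 42)
  ref <- d$group == "pasture"
  # reference library is P-enriched: more defined C/P and lower values
  expect_gt(mean(!is.na(d$cp[ref])), mean(!is.na(d$cp[!ref])))
  expect_lt(median(d$cp[ref], na.rm = TRUE), median(d$cp[!ref], na.rm = TRUE))
  expect_lt(median(d$np[ref], na.rm = TRUE), median(d$np[!ref], na.rm = TRUE))
  # the no-shift control shares one composition: group medians agree to
  # within sampling noise
  d0 <- simulate_stoich_cohort(200, shift = FALSE, seed = 42)
  m_ref <- median(d0$cp[d0$group == "pasture"], na.rm = TRUE)
  m_oth <- median(d0$cp[d0$group != "pasture"], na.rm = TRUE)
  expect_lt(abs(m_ref - m_oth) / m_oth, 0.5)
})

test_that("degenerate designs are rejected", {
  expect_error(synthetic_design(groups = "only_one"), "length")
  design <- synthetic_design(groups = c("a", "b"), n_per_group = 2, seed = 1)
  lib <- sample_formula_library(10, c(85, 400), seed = 1)
  expect_error(simulate_feature_table(design, lib, noise_sdlog = -1, seed = 1))
  d1 <- study_design(c("x1", "x2", "y1"), c("x", "x", "y"), FALSE, "x")
  expect_error(simulate_feature_table(d1, lib, seed = 1), ">= 2 samples")
})
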