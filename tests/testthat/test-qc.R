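# QA/QC gates: blank retention, internal-standard CV, mass normalisation.

test_that("the strict >3x blank rule retains exactly the hand-derived features", {
  toy <- toy_blank_table()
  kept <- blank_filter(toy$table, toy$design, ratio = 3)
  # sample/blank means: 400/100 kept, 300/100 boundary removed, 50/0 kept
  # (zero blank signal), 10/100 removed, 90/30 boundary removed
  expect_identical(kept$features$feature_id, c("f1", "f3"))
  log <- attr(kept, "qc_log")
  expect_identical(log$features_in, 5L)
  expect_identical(log$features_out, 2L)
})

test_that("blank filtering is idempotent and honours ratio = 0", {
  toy <- toy_blank_table()
  once <- blank_filter(toy$table, toy$design)
  twice <- blank_filter(once, toy$design)
  expect_identical(once$features, twice$features)
  expect_identical(once$intensities, twice$intensities)
  # ratio 0: every feature with positive non-blank mean survives
  all_kept <- blank_filter(toy$table, toy$design, ratio = 0)
  expect_identical(all_kept$features$feature_id, paste0("f", 1:5))
  # max-blank statistic available by config
  expect_identical(
    blank_filter(toy$table, toy$design, blank_stat = "max")$features$feature_id,
    c("f1", "f3")
  )
})

test_that("blank filtering without blanks tells the caller to skip", {
  toy <- toy_blank_table()
  no_blank <- study_design(c("s1", "s2"), c("grass", "grass"), FALSE, "grass")
  tab <- feature_table(toy$table$features, toy$table$intensities[, 1:2])
  expect_error(blank_filter(tab, no_blank), "skip")
})

test_that("internal-standard CV matches hand calculations and is scale-invariant", {
  feats <- data.frame(feature_id = c("is1", "is2"), mz = c(150.1, 160.1),
                      rt_min = c(1, 2))
  design <- study_design(c("s1", "s2", "s3"), rep("g", 3), FALSE, "g")
  flat <- feature_table(feats, matrix(500, 2, 3,
                                      dimnames = list(NULL, design$sample_id)))
  expect_identical(internal_standard_cv(flat, "is1", design)$cv_pct, 0)

  raw <- rbind(c(1, 2, 3), c(10, 20, 30))
  colnames(raw) <- design$sample_id
  tab <- feature_table(feats, raw)
  cv <- internal_standard_cv(tab, "is1", design)
  expect_equal(cv$cv_pct, 50) # sd 1, mean 2
  expect_false(cv$pass) # 50% exceeds the default 30% acceptance threshold
  expect_true(internal_standard_cv(tab, "is1", design, threshold = 60)$pass)
  # multiplying all intensities by c > 0 leaves the CV unchanged
  tab10 <- feature_table(feats, tab$intensities * 17)
  expect_equal(internal_standard_cv(tab10, "is1", design)$cv_pct, 50)
  expect_equal(internal_standard_cv(tab, "is2", design)$cv_pct, 50)

  zero <- feature_table(feats, matrix(0, 2, 3,
                                      dimnames = list(NULL, design$sample_id)))
  expect_error(internal_standard_cv(zero, "is1", design), "zero mean")
  expect_error(internal_standard_cv(tab, "nope", design), "not present")
})

test_that("mass normalisation divides by sample mass and round-trips", {
  feats <- data.frame(feature_id = paste0("f", 1:3), mz = c(100.5, 200.5, 300.5),
                      rt_min = 1:3)
  raw <- matrix(c(60, 60, 90, 90, 120, 120), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("s1", "s2")))
  tab <- feature_table(feats, raw)
  design <- study_design(c("s1", "s2"), c("g", "g"), FALSE, "g",
                         mass_mg = c(30, 15))
  norm <- mass_normalize(tab, design)
  # equal raw intensities, half the mass: second sample doubles
  expect_equal(norm$intensities[, "s2"], 2 * norm$intensities[, "s1"])
  back <- sweep(norm$intensities, 2, c(30, 15), `*`)
  expect_equal(unname(back), unname(raw), tolerance = 1e-12)

  bad <- study_design(c("s1", "s2"), c("g", "g"), FALSE, "g",
                      mass_mg = c(30, NA))
  expect_error(mass_normalize(tab, bad), "s2")
})

test_that("injection-order drift is reported but changes nothing", {
  design <- synthetic_design(seed = 3)
  lib <- sample_formula_library(10, c(85, 400), seed = 1)
  sim <- simulate_feature_table(design, lib, seed = 3)
  drift <- injection_order_drift(sim$table, "IS_tryptophan", sim$design)
  expect_identical(nrow(drift), 1L)
  expect_true(is.finite(drift$slope))
  expect_identical(drift$n, sum(!design$is_blank))
})
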