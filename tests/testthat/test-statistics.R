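# Preprocessing transforms and group-level statistics.

test_that("quantile normalisation equalises column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))
  same <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)
  set.seed(4)
  r <- matrix(rlnorm(200), 20, 10, dimnames = list(NULL, paste0("s", 1:10)))
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_error(quantile_normalize(matrix(0, 3, 3)), "all-zero")
})

test_that("IQR filtering drops the lowest-spread features deterministically", {
  m <- rbind(
    f1 = c(1, 5, 9, 13),
    f2 = c(2, 2.1, 2.2, 2.3),
    f3 = c(0, 10, 20, 30),
    f4 = c(7, 7, 7, 7)
  )
  expect_identical(iqr_filter(m, 0), m)
  kept <- iqr_filter(m, 0.25)
  expect_identical(rownames(kept), c("f1", "f2", "f3")) # constant f4 dropped
  kept2 <- iqr_filter(m, 0.5)
  expect_identical(rownames(kept2), c("f1", "f3"))
})

test_that("log + Pareto scaling matches its defining identities", {
  # one feature whose logged values are {0, 2}: scaled = (x - 1)/2^(1/4)
  m <- matrix(c(1, exp(2)), 1, 2, dimnames = list("f", c("a", "b")))
  sc <- log_pareto(m, offset = 0)
  expect_equal(unname(sc[1, ]), c(-1, 1) / 2^0.25, tolerance = 1e-12)

  set.seed(9)
  r <- matrix(rlnorm(300), 30, 10)
  sc <- log_pareto(r)
  off <- attr(sc, "offset")
  lg <- log(r + off)
  expect_equal(apply(sc, 1, var), apply(lg, 1, sd), tolerance = 1e-10)

  const <- rbind(f1 = rep(5, 4), f2 = c(1, 2, 3, 4))
  sc2 <- log_pareto(const)
  expect_true(all(sc2["f1", ] == 0))
  expect_identical(attr(sc2, "constant_features"), "f1")
})

test_that("Kruskal-Wallis reproduces hand-derived statistics", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-10) # 3.857
  expect_equal(kw$df, 1)
  flat <- kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))
  expect_identical(flat$statistic, 0)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(10)
  x <- rnorm(12)
  g <- rep(c("a", "b", "c"), 4)
  h0 <- kruskal_wallis(x, g)$statistic
  expect_equal(kruskal_wallis(exp(x), g)$statistic, h0)
  expect_equal(kruskal_wallis(x^3, g)$statistic, h0)
  expect_equal(kruskal_wallis(rank(x), g)$statistic, h0)
})

test_that("the exhaustive permutation p-value enumerates the label null", {
  # {1,2,3} vs {4,5,6}: 20 assignments, only the two extreme ones reach the
  # observed H, so p_exact = 0.1
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                       exact = TRUE)
  expect_equal(kw$p_exact, 2 / 20)
  expect_error(kruskal_wallis(1:12, rep(c("a", "b"), 6), exact = TRUE),
               "n <= 10")
})

test_that("pairwise effect sizes follow their definitions and sign convention", {
  # identical distributions: d = 0, negligible
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("ref", "x"), each = 3)
  pw <- pairwise_vs_reference(v, g, "ref")
  expect_equal(pw$cohens_d, 0)
  expect_identical(pw$effect_label, "negligible")

  # means 1 vs 0, pooled sd exactly 1: d = +1, large
  v2 <- c(-1, 0, 1, 0, 1, 2)
  pw2 <- pairwise_vs_reference(v2, g, "ref")
  expect_equal(pw2$cohens_d, 1)
  expect_identical(pw2$effect_label, "large")
  expect_gt(pw2$cohens_d, 0) # comparison mean above reference: positive

  # disjoint distributions: Cliff's delta = 1
  v3 <- c(1, 2, 3, 10, 11, 12)
  pw3 <- pairwise_vs_reference(v3, g, "ref")
  expect_identical(pw3$cliffs_delta, 1)
  expect_error(pairwise_vs_reference(v3[1:3], g[1:3], "nope"), "reference")
})

test_that("significant feature sets recover planted fold changes", {
  n_feat <- 300
  planted <- 101:160
  recovered <- 0
  false_hits <- 0
  for (s in 1:20) {
    design <- synthetic_design(groups = c("pasture", "treat"), n_per_group = 4,
                               n_blanks = 0, seed = s)
    lib <- sample_formula_library(n_feat, c(85, 500), seed = s)
    eff <- numeric(n_feat)
    eff[planted] <- 2 # 4-fold
    sim <- simulate_feature_table(design, lib, effects = list(treat = eff),
                                  blank_fraction = 0, background_fraction = 0,
                                  internal_standards = FALSE, seed = s + 100)
    sets <- significant_feature_sets(sim$table, sim$design)
    hit <- sim$truth$feature_id[planted] %in% sets$treat
    recovered <- recovered + sum(hit)
    false_hits <- false_hits +
      sum(!sets$treat %in% sim$truth$feature_id[planted])
  }
  expect_gte(recovered / (20 * length(planted)), 0.8)
  expect_lte(false_hits / (20 * (n_feat - length(planted))), 0.05)
})

test_that("significance gates behave at their extremes", {
  design <- synthetic_design(groups = c("pasture", "treat"), n_per_group = 4,
                             n_blanks = 0, seed = 1)
  lib <- sample_formula_library(50, c(85, 500), seed = 1)
  sim <- simulate_feature_table(design, lib, effects = list(treat = 3),
                                internal_standards = FALSE, seed = 2)
  zero <- significant_feature_sets(sim$table, sim$design, alpha = 0)
  expect_identical(lengths(zero)[["treat"]], 0L)
  sets <- significant_feature_sets(sim$table, sim$design)
  expect_true(all(sets$treat %in% sim$table$features$feature_id))
})

test_that("UpSet counts are exclusive and partition the union", {
  u <- upset_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  get <- function(cb) u$count[u$combination == cb]
  expect_identical(get("A"), 1L)
  expect_identical(get("B"), 1L)
  expect_identical(get("A&B"), 2L)

  d <- upset_counts(list(x = "a", y = "b", z = "c"))
  expect_identical(d$count[d$degree == 1], c(1L, 1L, 1L))
  expect_true(all(d$count[d$degree > 1] == 0L))

  set.seed(11)
  sets <- lapply(1:4, function(i) as.character(sample(1:40, sample(5:20, 1))))
  names(sets) <- letters[1:4]
  u2 <- upset_counts(sets)
  expect_identical(sum(u2$count), length(unique(unlist(sets))))
})

test_that("per-group ratio values follow the presence rule", {
  design <- synthetic_design(groups = c("pasture", "treat"), n_per_group = 3,
                             n_blanks = 0, seed = 1)
  feats <- data.frame(feature_id = c("f1", "f2"), mz = c(100.5, 200.5),
                      rt_min = c(1, 2))
  # f1 only abundant in treat, f2 abundant everywhere
  inten <- rbind(c(1, 1, 1, 100, 100, 100), c(50, 50, 50, 60, 60, 60))
  colnames(inten) <- design$sample_id
  tab <- feature_table(feats, inten)
  ratios <- data.frame(feature_id = c("f1", "f2"), cn = c(2, 3),
                       cp = c(NA, 5), np = c(NA, 1.5))
  long <- ratio_values_by_group(tab, ratios, design)
  expect_identical(long$feature_id[long$group == "pasture"], "f2")
  expect_setequal(long$feature_id[long$group == "treat"], c("f1", "f2"))
})
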