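# PLS-DA: fitting, VIP scores and cross-validated Q2.

test_that("component 1 separates two well-separated point clouds", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, -4), 8, 5), matrix(rnorm(40, 4), 8, 5))
  y <- rep(c("lo", "hi"), each = 8)
  fit <- plsda_fit(X, y, 1)
  t1 <- fit$T_scores[, 1]
  expect_gt(min(t1[y == "hi"]) - max(t1[y == "lo"]), 0)
})

test_that("fitting is deterministic and sign-fixed", {
  d <- separated_cohort(2)
  a <- plsda_fit(d$X, d$y, 3)
  b <- plsda_fit(d$X, d$y, 3)
  expect_identical(a, b)
  for (k in 1:3) expect_gt(a$W[which.max(abs(a$W[, k])), k], 0)
  expect_error(plsda_fit(d$X, rep("one", nrow(d$X)), 2), ">= 2 classes")
  expect_error(plsda_fit(d$X, d$y, 1000), "n_components")
})

test_that("duplicating every variable preserves scores up to scale and VIPs", {
  d <- separated_cohort(3, p = 40)
  fit1 <- plsda_fit(d$X, d$y, 2)
  Xd <- cbind(d$X, d$X)
  colnames(Xd) <- paste0("v", seq_len(ncol(Xd)))
  fit2 <- plsda_fit(Xd, d$y, 2)
  for (k in 1:2) {
    expect_gt(abs(cor(fit1$T_scores[, k], fit2$T_scores[, k])), 1 - 1e-8)
  }
  v1 <- vip_scores(fit1)
  v2 <- vip_scores(fit2)
  p <- ncol(d$X)
  # each duplicate carries the same importance as its twin and as the
  # single-copy fit; the mean-square-1 normalisation still holds
  expect_equal(unname(v2[1:p]), unname(v2[p + 1:p]), tolerance = 1e-6)
  expect_equal(unname(v2[1:p]), unname(v1), tolerance = 1e-6)
  expect_equal(mean(v2^2), 1, tolerance = 1e-8)
})

test_that("VIP mean square is 1 and symmetric inputs give VIP 1", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(12:24, 1)
    p <- sample(10:60, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(rep(c("a", "b", "c"), length.out = n))
    fit <- plsda_fit(X, y, 2)
    expect_equal(mean(vip_scores(fit)^2), 1, tolerance = 1e-8)
    expect_equal(mean(vip_scores(fit, 1)^2), 1, tolerance = 1e-8)
  }
  # all variables identical: every VIP equals 1 by symmetry
  base <- rnorm(18)
  Xs <- matrix(base, 18, 7)
  ys <- rep(c("a", "b"), 9)
  fits <- plsda_fit(Xs, ys, 1)
  expect_equal(unname(vip_scores(fits)), rep(1, 7), tolerance = 1e-8)
})

test_that("a single informative variable attains the maximal VIP", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 16
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 7] <- ifelse(y == "a", -2, 2) + rnorm(n, 0, 0.3)
    fit <- plsda_fit(X, y, 2)
    which.max(vip_scores(fit)) == 7
  }, logical(1))
  expect_true(all(hits))
})

test_that("cross-validation separates signal from permuted labels", {
  d <- separated_cohort(5)
  cv <- cross_validate(d$X, d$y, k = 5, n_components = 5, seed = 5)
  expect_gt(cv$q2, 0.7)
  expect_gte(cv$r2, cv$q2)
  expect_lte(cv$r2, 1)
  set.seed(6)
  cvp <- cross_validate(d$X, sample(d$y), k = 5, n_components = 5, seed = 6)
  expect_lt(cvp$q2, 0.2)
  expect_error(cross_validate(d$X, d$y, k = 1), "k >= 2")
})

test_that("R2 >= Q2 across repeated random cohorts", {
  res <- vapply(1:20, function(s) {
    d <- separated_cohort(s, between_sd = 1.5)
    cv <- cross_validate(d$X, d$y, k = 5, n_components = 3, seed = s)
    cv$r2 - cv$q2
  }, numeric(1))
  expect_true(all(res >= 0))
})

test_that("the NIPALS fit agrees with the mixOmics reference implementation", {
  d <- separated_cohort(8, p = 60)
  fit <- plsda_fit(d$X, d$y, 2)
  mo <- mixOmics::plsda(d$X, factor(d$y), ncomp = 2, scale = FALSE)
  for (k in 1:2) {
    expect_gt(abs(cor(fit$T_scores[, k], mo$variates$X[, k])), 0.999)
  }
  vm <- mixOmics::vip(mo)[, 2]
  expect_equal(unname(vip_scores(fit)), unname(vm), tolerance = 0.01)
})

test_that("prediction recovers training classes on separated data", {
  d <- separated_cohort(9)
  fit <- plsda_fit(d$X, d$y, 5)
  pred <- predict(fit, d$X)
  expect_identical(pred$class, d$y)
})
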