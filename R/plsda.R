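# PLS-DA: NIPALS PLS2 regression of a one-hot class matrix on the data
# matrix, VIP feature importance and stratified k-fold R2/Q2 validation.

one_hot <- function(y) {
  y <- as.factor(y)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

#' Fit a PLS-DA model
#'
#' PLS2 regression (NIPALS) of the column-centred one-hot class matrix Y on
#' the column-centred data matrix X. The fit is deterministic given the input
#' order: the NIPALS start vector is the Y column with the largest variance
#' (first on ties) and each component's sign is fixed so that its
#' largest-magnitude X-weight is positive.
#'
#' @param X Numeric matrix, samples x variables.
#' @param y Class labels (>= 2 classes).
#' @param n_components Number of latent components (>= 1, at most
#'   `min(nrow(X) - 1, ncol(X))`).
#' @param max_iter,tol NIPALS iteration controls.
#' @return Object of class `plsda`: weights `W`, X-loadings `P`, Y-loadings
#'   `C`, scores `T_scores`, per-component explained Y sum of squares `ssy`,
#'   cumulative `r2` (fraction of class-matrix variance explained), centring
#'   vectors and class levels.
#' @export
plsda_fit <- function(X, y, n_components = 2, max_iter = 500, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("PLS-DA needs >= 2 classes")
  stopifnot(nrow(X) == length(y), n_components >= 1)
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    stop("n_components must be <= min(samples - 1, variables)")
  }
  Y <- one_hot(y)
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  E <- sweep(X, 2, x_center)
  F_ <- sweep(Y, 2, y_center)
  tss_y <- sum(F_^2)

  nvar <- ncol(X)
  W <- matrix(0, nvar, n_components)
  P <- matrix(0, nvar, n_components)
  C <- matrix(0, ncol(Y), n_components, dimnames = list(colnames(Y), NULL))
  T_scores <- matrix(0, nrow(X), n_components)
  ssy <- numeric(n_components)

  for (a in seq_len(n_components)) {
    u <- F_[, which.max(apply(F_, 2, stats::var))]
    if (sum(u^2) < .Machine$double.eps) break
    t_old <- rep(Inf, nrow(E))
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      cc <- crossprod(F_, t_) / sum(t_^2)
      u <- F_ %*% cc / sum(cc^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    j <- which.max(abs(w))
    if (w[j] < 0) {
      w <- -w; t_ <- -t_; cc <- -cc
    }
    p <- crossprod(E, t_) / sum(t_^2)
    ssy[a] <- sum(t_^2) * sum(cc^2)
    E <- E - t_ %*% t(p)
    F_ <- F_ - t_ %*% t(cc)
    W[, a] <- w
    P[, a] <- p
    C[, a] <- cc
    T_scores[, a] <- t_
  }
  structure(
    list(
      n_components = n_components, W = W, P = P, C = C, T_scores = T_scores,
      ssy = ssy, tss_y = tss_y, r2 = sum(ssy) / tss_y,
      x_center = x_center, y_center = y_center, levels = levels(y),
      variables = colnames(X)
    ),
    class = "plsda"
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat("<plsda>", length(x$levels), "classes,", x$n_components,
      "components, R2 =", format(x$r2, digits = 4), "\n")
  invisible(x)
}

#' Predict class membership from a PLS-DA model
#'
#' Reconstructs the PLS regression coefficients `B = W (P'W)^-1 C'` and
#' returns the predicted (centred-back) class matrix together with the
#' highest-scoring class per sample.
#'
#' @param object A [plsda_fit()] model.
#' @param newdata Numeric matrix with the same variables as the training X.
#' @param ... Ignored.
#' @return List: `Y_hat` (samples x classes) and `class` (character).
#' @export
predict.plsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  B <- object$W %*% solve(crossprod(object$P, object$W)) %*% t(object$C)
  Yhat <- sweep(newdata, 2, object$x_center) %*% B
  Yhat <- sweep(Yhat, 2, object$y_center, `+`)
  list(Y_hat = Yhat, class = object$levels[max.col(Yhat, ties.method = "first")])
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP over the first `components` latent variables:
#' `vip_j = sqrt( p * sum_a(ssy_a * w_aj^2) / sum_a(ssy_a) )` with `p` the
#' number of variables, `ssy_a` the Y sum of squares explained by component a
#' and `w` the normalised NIPALS weights. The mean of the squared VIPs over
#' variables is exactly 1; variables with VIP > 1 contribute more than
#' average to class separation.
#'
#' @param model A [plsda_fit()] model.
#' @param components Components to accumulate (default: all fitted). Use
#'   `components = 1` for component-1 VIPs.
#' @return Named numeric vector of VIP scores (one per variable).
#' @export
vip_scores <- function(model, components = NULL) {
  stopifnot(inherits(model, "plsda"))
  a <- if (is.null(components)) seq_len(model$n_components) else components
  stopifnot(all(a >= 1), all(a <= model$n_components))
  W <- model$W[, a, drop = FALSE]
  ssy <- model$ssy[a]
  nvar <- nrow(W)
  vip <- sqrt(nvar * as.numeric(W^2 %*% ssy) / sum(ssy))
  names(vip) <- model$variables
  vip
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt to folds round-robin, so classes stay balanced across folds (classes
# smaller than k simply appear in a subset of folds).
stratified_folds <- function(y, k, seed = 0) {
  y <- as.factor(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' k-fold cross-validated R2 and Q2 for PLS-DA
#'
#' R2 comes from the full fit (cumulative fraction of class-matrix variance
#' explained). Q2 is `1 - PRESS / TSS` where PRESS pools the squared
#' prediction errors of the centred one-hot class matrix over the stratified
#' held-out folds, and TSS is the total sum of squares about the overall
#' class means. Folds are seeded for reproducibility.
#'
#' @param X Numeric matrix, samples x variables.
#' @param y Class labels.
#' @param k Number of folds (>= 2, default 5).
#' @param n_components Latent components for every fold model.
#' @param seed Fold-assignment seed (default 0).
#' @return List: `r2`, `q2`, `press`, `tss`, `folds`.
#' @export
cross_validate <- function(X, y, k = 5, n_components = 2, seed = 0) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(k >= 2, nrow(X) == length(y))
  folds <- stratified_folds(y, k, seed)
  Y <- one_hot(y)
  press <- 0
  for (f in sort(unique(folds))) {
    test <- folds == f
    if (nlevels(droplevels(y[!test])) < 2) {
      stop("a training fold lost all but one class; reduce k")
    }
    fit <- plsda_fit(X[!test, , drop = FALSE], droplevels(y[!test]),
                     n_components = min(n_components, sum(!test) - 1))
    pred <- predict(fit, X[test, , drop = FALSE])$Y_hat
    # align class columns (a fold can drop a class entirely)
    Yhat <- matrix(0, sum(test), ncol(Y), dimnames = list(NULL, colnames(Y)))
    Yhat[, colnames(pred)] <- pred
    press <- press + sum((Y[test, , drop = FALSE] - Yhat)^2)
  }
  tss <- sum(sweep(Y, 2, colMeans(Y))^2)
  full <- plsda_fit(X, y, n_components = n_components)
  list(r2 = full$r2, q2 = 1 - press / tss, press = press, tss = tss,
       folds = folds)
}
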