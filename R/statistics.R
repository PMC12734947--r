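# Intensity preprocessing and group-level statistics: quantile normalisation,
# IQR filtering, log + Pareto scaling, Kruskal-Wallis, pairwise contrasts
# against the reference group with effect sizes, volcano-style significant
# feature sets and UpSet-style exclusive intersection counts.

#' Quantile-normalise an intensity matrix
#'
#' Forces every sample (column) onto the identical intensity distribution:
#' each column's sorted values are replaced by the row-wise mean of the
#' sorted columns, with ties averaged (delegated to
#' `limma::normalizeQuantiles`).
#'
#' @param mat Numeric matrix, features x samples (>= 2 samples).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  if (all(mat == 0)) stop("cannot quantile-normalise an all-zero matrix")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Filter features by interquartile range
#'
#' Removes the `drop_fraction` of features with the smallest IQR across
#' samples (near-constant features carry no discriminating signal). The
#' number dropped is `floor(drop_fraction * nrow)`; ties are broken
#' deterministically by feature id (row name/order).
#'
#' @param mat Numeric matrix, features x samples.
#' @param drop_fraction Fraction in [0, 1) of features to drop (default
#'   0.25).
#' @return The filtered matrix, row order preserved.
#' @export
iqr_filter <- function(mat, drop_fraction = 0.25) {
  stopifnot(is.matrix(mat), drop_fraction >= 0, drop_fraction < 1)
  n_drop <- floor(drop_fraction * nrow(mat))
  if (n_drop == 0) return(mat)
  iqr <- apply(mat, 1, stats::IQR, type = 7)
  ord <- order(iqr, seq_len(nrow(mat)))
  drop <- ord[seq_len(n_drop)]
  mat[-drop, , drop = FALSE]
}

#' Log-transform and Pareto-scale an intensity matrix
#'
#' Per feature (row): `x -> (log(x + offset) - mean) / sqrt(sd)`, where mean
#' and sd are taken over the logged values. Pareto scaling (dividing by the
#' square root of the standard deviation) sits between mean centering and
#' unit-variance scaling; after it each feature's variance equals the
#' standard deviation of its logged values. The offset handling zeros
#' defaults to half the smallest positive value in the matrix. Zero-variance
#' features are left centred (all zeros) and flagged in the
#' `constant_features` attribute.
#'
#' @param mat Numeric matrix, features x samples, intensities >= 0.
#' @param offset Additive offset before the log; `NULL` for the default.
#' @return The transformed matrix, with attributes `offset` and
#'   `constant_features`.
#' @export
log_pareto <- function(mat, offset = NULL) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  if (is.null(offset)) {
    pos <- mat[mat > 0]
    offset <- if (length(pos)) min(pos) / 2 else 1
  }
  lg <- log(mat + offset)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, stats::sd)
  constant <- sdv == 0
  scl <- ifelse(constant, 1, sqrt(sdv))
  out <- (lg - mu) / scl
  attr(out, "offset") <- offset
  attr(out, "constant_features") <- rownames(mat)[constant]
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (`stats::kruskal.test`), plus an exhaustive-permutation p-value for small
#' samples (`exact = TRUE`, total n <= 10): the proportion of label
#' permutations whose H is at least the observed H.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each with >= 1 value).
#' @param exact Also compute the exhaustive permutation p-value.
#' @return List: `statistic` (H), `df`, `p_value` (chi-square), and
#'   `p_exact` when requested.
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(droplevels(groups)) < 2) stop("Kruskal-Wallis needs >= 2 groups")
  if (length(unique(values)) == 1) {
    # fully tied data carry no rank information: H = 0 by convention
    out <- list(statistic = 0, df = nlevels(droplevels(groups)) - 1,
                p_value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    out <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  }
  if (exact) {
    n <- length(values)
    if (n > 10) stop("exact permutation p is limited to n <= 10")
    perms <- label_permutations(as.integer(groups))
    h_obs <- out$statistic
    h_all <- apply(perms, 2, function(lab) kw_statistic(values, lab))
    out$p_exact <- mean(h_all >= h_obs - 1e-10)
  }
  out
}

# Tie-corrected H computed from ranks (used for the permutation null).
kw_statistic <- function(values, lab) {
  r <- rank(values)
  n <- length(values)
  sums <- tapply(r, lab, sum)
  sizes <- tabulate(lab)
  sizes <- sizes[sizes > 0]
  h <- 12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0) # fully tied data
  h / corr
}

# All distinct assignments of a label multiset (columns = assignments).
label_permutations <- function(lab) {
  n <- length(lab)
  counts <- tabulate(lab)
  k <- length(counts)
  slots <- seq_len(n)
  assemble <- function(remaining, g) {
    if (g == k) {
      out <- integer(n)
      out[remaining] <- k
      return(matrix(out, ncol = 1))
    }
    picks <- utils::combn(remaining, counts[g])
    res <- lapply(seq_len(ncol(picks)), function(i) {
      sub <- assemble(setdiff(remaining, picks[, i]), g + 1)
      sub[picks[, i], ] <- g
      sub
    })
    do.call(cbind, res)
  }
  assemble(slots, 1)
}

cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  diff <- mean(x) - mean(y)
  if (sp2 == 0) {
    return(if (diff == 0) 0 else sign(diff) * Inf)
  }
  diff / sqrt(sp2)
}

cliffs_delta <- function(x, y) {
  g <- outer(x, y, `>`)
  l <- outer(x, y, `<`)
  (sum(g) - sum(l)) / (length(x) * length(y))
}

effect_label <- function(d) {
  a <- abs(d)
  if (is.na(a)) NA_character_
  else if (a < 0.2) "negligible"
  else if (a < 0.5) "small"
  else if (a < 0.8) "medium"
  else "large"
}

#' Pairwise comparisons against the reference group
#'
#' For each non-reference group: a two-sided Mann-Whitney U test against the
#' reference plus effect sizes - Cohen's d (pooled-SD, on the raw value
#' scale; positive when the comparison group's mean exceeds the
#' reference's) as the primary measure with the rank-based Cliff's delta
#' reported alongside, and the conventional qualitative label at |d|
#' cutpoints 0.2 / 0.5 / 0.8.
#'
#' @param values Numeric vector (e.g. one stoichiometric ratio per feature).
#' @param groups Group label per value.
#' @param reference Reference group name.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return data.frame, one row per non-reference group: `group`, `n`,
#'   `n_reference`, `p_value`, `cohens_d`, `cliffs_delta`, `effect_label`,
#'   `significant`.
#' @export
pairwise_vs_reference <- function(values, groups, reference, alpha = 0.05) {
  groups <- as.character(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  ref <- values[groups == reference]
  if (!length(ref)) stop("reference group '", reference, "' has no values")
  others <- setdiff(unique(groups), reference)
  rows <- lapply(others, function(g) {
    x <- values[groups == g]
    if (!length(x)) stop("comparison group '", g, "' has no values")
    p <- stats::wilcox.test(x, ref, exact = FALSE)$p.value
    d <- cohens_d(x, ref)
    data.frame(
      group = g, n = length(x), n_reference = length(ref), p_value = p,
      cohens_d = d, cliffs_delta = cliffs_delta(x, ref),
      effect_label = effect_label(d), significant = p < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group stoichiometric ratio values from a feature table
#'
#' Assigns each feature's composite ratios to the groups where the feature is
#' abundant: a feature contributes to group g when its mean intensity in g is
#' at least `presence_fraction` of its maximum group mean. This converts one
#' feature table plus per-feature ratios into the per-group ratio
#' distributions that the group comparisons consume.
#'
#' @param table A [feature_table()] (post-QC).
#' @param ratios Output of [feature_ratios()].
#' @param design A [study_design()].
#' @param presence_fraction Abundance threshold relative to the feature's
#'   maximum group mean (default 0.5).
#' @return Long data.frame: `group`, `feature_id`, `cn`, `cp`, `np`.
#' @export
ratio_values_by_group <- function(table, ratios, design,
                                  presence_fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "study_design"),
            presence_fraction > 0, presence_fraction <= 1)
  groups <- unique(design$group[!design$is_blank])
  ids <- intersect(table$features$feature_id, ratios$feature_id)
  gm <- sapply(groups, function(g) {
    cols <- design$sample_id[!design$is_blank & design$group == g]
    rowMeans(table$intensities[ids, cols, drop = FALSE])
  })
  gm <- matrix(gm, nrow = length(ids), dimnames = list(ids, groups))
  present <- gm >= presence_fraction * apply(gm, 1, max)
  r <- ratios[match(ids, ratios$feature_id), ]
  rows <- lapply(groups, function(g) {
    sel <- present[, g]
    data.frame(group = g, feature_id = ids[sel],
               cn = r$cn[sel], cp = r$cp[sel], np = r$np[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano-style significant feature sets per group
#'
#' For each non-reference group, the set of features passing both a p-value
#' gate (Welch t-test on log intensities vs the reference group, with
#' optional Benjamini-Hochberg correction across features) and a fold-change
#' gate (|log2 of the group-mean ratio| on the raw scale). The gates default
#' to p < 0.05 after BH and |log2 FC| >= 1.
#'
#' @param table A [feature_table()] (post-QC, raw intensities).
#' @param design A [study_design()].
#' @param alpha p-value gate (default 0.05).
#' @param min_abs_log2fc Fold-change gate (default 1).
#' @param p_adjust `"BH"` (default) or `"none"`.
#' @return Named list (one element per non-reference group) of feature-id
#'   character vectors.
#' @export
significant_feature_sets <- function(table, design, alpha = 0.05,
                                     min_abs_log2fc = 1,
                                     p_adjust = c("BH", "none")) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "study_design"),
            alpha >= 0, min_abs_log2fc >= 0)
  p_adjust <- match.arg(p_adjust)
  ref <- reference_group(design)
  groups <- setdiff(unique(design$group[!design$is_blank]), ref)
  ref_cols <- design$sample_id[!design$is_blank & design$group == ref]
  inten <- table$intensities
  pos <- inten[inten > 0]
  offset <- if (length(pos)) min(pos) / 2 else 1
  lg <- log(inten + offset)
  out <- lapply(groups, function(g) {
    cols <- design$sample_id[!design$is_blank & design$group == g]
    p <- vapply(seq_len(nrow(inten)), function(i) {
      x <- lg[i, cols]; y <- lg[i, ref_cols]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        return(if (mean(x) == mean(y)) 1 else 0)
      }
      stats::t.test(x, y)$p.value
    }, numeric(1))
    if (p_adjust == "BH") p <- stats::p.adjust(p, "BH")
    fc <- log2(rowMeans(inten[, cols, drop = FALSE]) /
                 rowMeans(inten[, ref_cols, drop = FALSE]))
    table$features$feature_id[p < alpha & abs(fc) >= min_abs_log2fc &
                                is.finite(fc)]
  })
  stats::setNames(out, groups)
}

#' Exclusive intersection counts for an UpSet-style summary
#'
#' For every non-empty combination of set names, the number of ids belonging
#' to exactly that combination. The counts over all combinations partition
#' the union of the sets.
#'
#' @param sets Named list of character vectors.
#' @return data.frame: `combination` (names joined by `&`), `degree`,
#'   `count`, covering all 2^k - 1 combinations (zero counts included).
#' @export
upset_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)),
            all(nzchar(names(sets))))
  nms <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe), dimnames = list(NULL, nms))
  key <- apply(member, 1, function(r) paste(nms[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(nms), function(k) {
    apply(utils::combn(nms, k), 2, paste, collapse = "&")
  }))
  counts <- vapply(combos, function(cb) sum(key == cb), integer(1))
  data.frame(
    combination = combos,
    degree = lengths(strsplit(combos, "&", fixed = TRUE)),
    count = unname(counts),
    stringsAsFactors = FALSE
  )
}
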