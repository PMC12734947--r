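# Composite formulas and elemental stoichiometric ratios.

# Elementwise ratio with NA where the denominator is zero.
count_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Average top candidate formulas into a composite formula
#'
#' A composite formula carries the structural uncertainty of up to three
#' equally weighted candidate formulas into stoichiometry. Two averaging
#' modes are provided because "a simple average" of elemental ratios admits
#' both readings:
#'
#' * `"average-counts"` (default): element-wise arithmetic mean of the
#'   candidate counts; ratios are computed from the mean counts.
#' * `"average-ratios"`: each candidate's ratio is computed first and the
#'   defined ratios are averaged.
#'
#' The modes agree whenever all candidates share the denominator element
#' count, and both reduce to the single candidate when only one is given.
#'
#' @param cands Candidate data.frame (rows = candidates) with count columns
#'   `c,h,n,o,p,s`, typically from [rank_candidates()]; 1-3 rows.
#' @param mode Averaging mode.
#' @return List of class `composite_formula`: `counts` (mean counts, possibly
#'   fractional), `n_candidates`, `mode`, and `ratio_cn`, `ratio_cp`,
#'   `ratio_np` (NA when undefined).
#' @export
composite_formula <- function(cands, mode = c("average-counts", "average-ratios")) {
  mode <- match.arg(mode)
  if (is.null(nrow(cands)) || nrow(cands) == 0) stop("empty candidate list")
  if (nrow(cands) > 3) stop("composites average at most three ranked candidates")
  m <- as.matrix(cands[, ELEMENTS, drop = FALSE])
  counts <- colMeans(m)
  if (mode == "average-counts") {
    r <- c(
      ratio_cn = count_ratio(counts[["c"]], counts[["n"]]),
      ratio_cp = count_ratio(counts[["c"]], counts[["p"]]),
      ratio_np = count_ratio(counts[["n"]], counts[["p"]])
    )
  } else {
    avg <- function(num, den) {
      v <- count_ratio(m[, num], m[, den])
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    r <- c(ratio_cn = avg("c", "n"), ratio_cp = avg("c", "p"),
           ratio_np = avg("n", "p"))
  }
  structure(
    list(counts = counts, n_candidates = nrow(cands), mode = mode,
         ratio_cn = unname(r[["ratio_cn"]]), ratio_cp = unname(r[["ratio_cp"]]),
         ratio_np = unname(r[["ratio_np"]])),
    class = "composite_formula"
  )
}

#' Elemental ratios of a composite formula
#'
#' C/N, C/P and N/P from the composite mean counts. A ratio is undefined
#' (NA) exactly when its denominator mean count is zero; the feature is then
#' excluded from downstream statistics for that ratio only.
#'
#' @param comp A [composite_formula()].
#' @return Named numeric vector `c(cn, cp, np)` (NA = undefined).
#' @export
elemental_ratios <- function(comp) {
  stopifnot(inherits(comp, "composite_formula"))
  counts <- comp$counts
  c(
    cn = count_ratio(counts[["c"]], counts[["n"]]),
    cp = count_ratio(counts[["c"]], counts[["p"]]),
    np = count_ratio(counts[["n"]], counts[["p"]])
  )
}

#' Composite formulas and ratios for a whole assignment table
#'
#' Groups ranked candidates by feature and computes one composite per
#' feature.
#'
#' @param assignments Output of [assign_formulas()] (ranked candidates with a
#'   `feature_id` column).
#' @param mode Averaging mode, see [composite_formula()].
#' @return data.frame: `feature_id`, mean counts `c,h,n,o,p,s`,
#'   `n_candidates`, `cn`, `cp`, `np` (NA markers for undefined ratios).
#' @export
feature_ratios <- function(assignments, mode = "average-counts") {
  if (!nrow(assignments)) {
    return(data.frame(feature_id = character(), c = numeric(), h = numeric(),
                      n = numeric(), o = numeric(), p = numeric(), s = numeric(),
                      n_candidates = integer(), cn = numeric(), cp = numeric(),
                      np = numeric(), stringsAsFactors = FALSE))
  }
  ids <- unique(assignments$feature_id)
  rows <- lapply(ids, function(id) {
    comp <- composite_formula(assignments[assignments$feature_id == id, ,
                                          drop = FALSE], mode)
    data.frame(feature_id = id, as.list(comp$counts),
               n_candidates = comp$n_candidates,
               cn = comp$ratio_cn, cp = comp$ratio_cp, np = comp$ratio_np,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' IQR-based outlier trim for display
#'
#' Returns the values inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 linear
#' interpolation quartiles), order preserved. Intended only for rendering
#' violin-style distribution plots; statistics are always computed on the
#' complete data.
#'
#' @param values Numeric vector, length >= 4.
#' @return The retained subset of `values`.
#' @export
ratio_outlier_trim <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("outlier trimming needs >= 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}
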