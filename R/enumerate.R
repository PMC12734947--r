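# Exhaustive CHNOPS formula enumeration within a ppm window, candidate
# ranking, and library matching for known metabolites.

# Cache of heteroatom (N,O,P,S) grids keyed by the bounds, so repeated
# enumeration over a feature table builds the grid once.
.grid_cache <- new.env(parent = emptyenv())

nops_grid <- function(bounds) {
  key <- paste(bounds[c("n", "o", "p", "s")], collapse = "_")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  g <- expand.grid(
    n = 0:bounds[["n"]], o = 0:bounds[["o"]],
    p = 0:bounds[["p"]], s = 0:bounds[["s"]],
    KEEP.OUT.ATTRS = FALSE
  )
  g <- as.matrix(g)
  mass <- g %*% MONOISOTOPIC_MASS[c("n", "o", "p", "s")]
  ord <- order(mass)
  res <- list(counts = g[ord, , drop = FALSE], mass = as.numeric(mass)[ord])
  .grid_cache[[key]] <- res
  res
}

# Neutral-mass search window implied by a ppm tolerance on the observed m/z:
# candidates are kept when |(mz_obs - mz_theo) / mz_theo| * 1e6 <= tol.
mass_window <- function(mz, tol_ppm) {
  lo <- mz / (1 + tol_ppm * 1e-6) + PROTON_MASS
  hi <- mz / (1 - tol_ppm * 1e-6) + PROTON_MASS
  c(lo, hi)
}

#' Enumerate candidate CHNOPS formulas for an observed m/z
#'
#' Exhaustively enumerates, within the configured element bounds, every
#' CHNOPS formula whose theoretical `[M-H]-` m/z lies within the ppm
#' tolerance of the observed m/z, then filters by [element_ratio_rules()] and
#' by [isotope_match_score()] against the observed isotope pattern (the
#' 5/5/5 placeholder when none is measured). An empty result is a valid
#' outcome: the feature simply remains unassigned (MSI level 4 without a
#' formula).
#'
#' Enumeration loops over a precomputed heteroatom (N, O, P, S) mass grid and
#' carbon count; the hydrogen count is then pinned by the narrow mass window,
#' so the search is exhaustive without a six-deep scan.
#'
#' @param mz Observed m/z (Th) of the deprotonated ion.
#' @param config A [formula_config()]; `config$ppm` overrides the
#'   mass-dependent default tolerance.
#' @param observed_pattern Optional measured A+1..A+3 abundances (% of A);
#'   defaults to `config$observed_pattern`.
#' @return A data.frame of candidates sorted by rank order (|ppm error|
#'   ascending, isotope score descending, Hill formula string), with columns
#'   `formula`,
#'   `c,h,n,o,p,s`, `theoretical_mass`, `theoretical_mz`, `mz_error_ppm`,
#'   `rdbe`, `isotope_score`, `nitrogen_rule_ok`.
#' @examples
#' enumerate_candidates(179.05617) # glucose [M-H]-
#' @export
enumerate_candidates <- function(mz, config = formula_config(),
                                 observed_pattern = NULL) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
  obs <- if (is.null(observed_pattern)) config$observed_pattern else observed_pattern
  neutral <- mz + PROTON_MASS
  tol <- if (is.null(config$ppm)) ppm_tolerance(neutral) else config$ppm
  win <- mass_window(mz, tol)

  grid <- nops_grid(config$bounds)
  keep <- grid$mass <= win[2] - config$min_c * 12
  gmass <- grid$mass[keep]
  gcounts <- grid$counts[keep, , drop = FALSE]

  mh <- MONOISOTOPIC_MASS[["h"]]
  rows <- vector("list", config$bounds[["c"]] + 1)
  c_range <- config$min_c:config$bounds[["c"]]
  for (cc in c_range) {
    rem_lo <- win[1] - gmass - 12 * cc
    rem_hi <- win[2] - gmass - 12 * cc
    hmin <- pmax(0, ceiling(rem_lo / mh - 1e-12))
    hmax <- pmin(config$bounds[["h"]], floor(rem_hi / mh + 1e-12))
    ok <- which(hmax >= hmin & rem_hi >= -1e-9)
    if (!length(ok)) {
      if (all(rem_hi < 0)) break # grid is mass-sorted: heavier c only worse
      next
    }
    # the window is far narrower than one hydrogen mass, so hmin == hmax
    # except in pathological wide-tolerance configs; expand just in case
    reps <- hmax[ok] - hmin[ok] + 1
    idx <- rep(ok, reps)
    h <- unlist(lapply(seq_along(ok), function(i) hmin[ok[i]]:hmax[ok[i]]))
    rows[[cc + 1]] <- cbind(c = cc, h = h, gcounts[idx, , drop = FALSE])
  }
  m <- do.call(rbind, rows)
  empty <- candidate_frame(NULL)
  if (is.null(m) || nrow(m) == 0) return(empty)
  m <- m[, ELEMENTS, drop = FALSE]

  theo_mass <- as.numeric(m %*% MONOISOTOPIC_MASS)
  theo_mz <- theo_mass - PROTON_MASS
  err_ppm <- (mz - theo_mz) / theo_mz * 1e6
  in_win <- abs(err_ppm) <= tol + 1e-12
  det <- rules_matrix(m, config)
  keep <- in_win & det$pass
  if (!any(keep)) return(empty)

  m <- m[keep, , drop = FALSE]
  cand <- data.frame(
    formula = apply(m, 1, function(r) format_formula(r[ELEMENTS])),
    m,
    theoretical_mass = theo_mass[keep],
    theoretical_mz = theo_mz[keep],
    mz_error_ppm = err_ppm[keep],
    rdbe = det$rdbe[keep],
    nitrogen_rule_ok = det$nitrogen_rule_ok[keep],
    stringsAsFactors = FALSE
  )
  cand$isotope_score <- vapply(seq_len(nrow(cand)), function(i) {
    theo <- theoretical_isotope_pattern(m[i, ])
    isotope_match_score(obs, theo, config$abundance_error)
  }, numeric(1))
  cand <- cand[cand$isotope_score >= config$min_isotope_score, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  ord <- order(abs(cand$mz_error_ppm), -cand$isotope_score, cand$formula)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cand$rank <- NA_integer_
  cand
}

candidate_frame <- function(x) {
  if (!is.null(x)) return(x)
  data.frame(
    formula = character(), c = numeric(), h = numeric(), n = numeric(),
    o = numeric(), p = numeric(), s = numeric(),
    theoretical_mass = numeric(), theoretical_mz = numeric(),
    mz_error_ppm = numeric(), rdbe = numeric(),
    nitrogen_rule_ok = logical(), isotope_score = numeric(),
    rank = integer(), stringsAsFactors = FALSE
  )
}

#' Select and rank the top candidate formulas
#'
#' Stable sort by absolute mass error in ppm (ascending), then isotope match
#' score (descending), then the Hill-order formula string (ascending, a
#' deterministic tiebreak), returning at most `k` candidates with their
#' `rank` field set. Mass error ranks first because it is the only
#' observation-driven evidence in an MS1-only workflow: when the placeholder
#' isotope pattern is in use the isotope score is a function of the candidate
#' alone and cannot distinguish the true formula from decoys, whereas the
#' measured m/z can.
#'
#' @param cands Candidate data.frame from [enumerate_candidates()].
#' @param k Maximum number of candidates to keep (default 3).
#' @return The top `min(k, nrow(cands))` rows, ranked 1..k.
#' @export
rank_candidates <- function(cands, k = 3) {
  stopifnot(k >= 1)
  if (!nrow(cands)) return(cands)
  ord <- order(abs(cands$mz_error_ppm), -cands$isotope_score, cands$formula)
  out <- cands[ord, , drop = FALSE][seq_len(min(k, nrow(cands))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign top-ranked candidate formulas to every feature of a table
#'
#' Runs [enumerate_candidates()] + [rank_candidates()] per feature. Features
#' with no surviving candidate are left unassigned and simply absent from the
#' result.
#'
#' @param table A [feature_table()].
#' @param config A [formula_config()].
#' @param k Candidates retained per feature (default 3).
#' @return data.frame of ranked candidates with a `feature_id` column.
#' @export
assign_formulas <- function(table, config = formula_config(), k = 3) {
  stopifnot(inherits(table, "feature_table"))
  res <- lapply(seq_len(nrow(table$features)), function(i) {
    cand <- rank_candidates(enumerate_candidates(table$features$mz[i], config), k)
    if (!nrow(cand)) return(NULL)
    cbind(feature_id = table$features$feature_id[i], cand,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- cbind(feature_id = character(), candidate_frame(NULL))
  }
  rownames(out) <- NULL
  out
}

#' Match features against a known-compound library
#'
#' A feature matches a library entry when the observed neutral mass (from
#' `[M-H]-`) is within `ppm` of the entry's neutral monoisotopic mass and the
#' retention times differ by at most `rt_window_min` minutes. When several
#' entries qualify the smallest |ppm error| wins. Unmatched features keep
#' `NA` annotations and remain MSI level 4.
#'
#' @param table A [feature_table()].
#' @param library data.frame with columns `name`, and `mass` (neutral Da)
#'   and/or `formula`, and `rt_min`; see [read_compound_library()].
#' @param ppm Mass tolerance in ppm (default 5).
#' @param rt_window_min Retention-time tolerance in minutes (default 1.5).
#' @return data.frame: `feature_id`, `name`, `mass_error_ppm`, `rt_error_min`,
#'   `msi_level` (1 for matched, 4 otherwise).
#' @export
match_library <- function(table, library, ppm = 5, rt_window_min = 1.5) {
  stopifnot(inherits(table, "feature_table"), nrow(library) > 0)
  if (is.null(library$mass)) library$mass <- NA_real_
  need <- is.na(library$mass)
  if (any(need)) {
    if (is.null(library$formula)) stop("library entries need a mass or a formula")
    library$mass[need] <- vapply(library$formula[need], monoisotopic_mass, numeric(1))
  }
  stopifnot(all(library$mass > 0), all(library$rt_min >= 0))
  feats <- table$features
  out <- data.frame(
    feature_id = feats$feature_id, name = NA_character_,
    mass_error_ppm = NA_real_, rt_error_min = NA_real_,
    msi_level = 4L, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(feats))) {
    neutral <- neutral_mass_from_mz(feats$mz[i])
    err_ppm <- (neutral - library$mass) / library$mass * 1e6
    rt_err <- feats$rt_min[i] - library$rt_min
    hit <- which(abs(err_ppm) <= ppm & abs(rt_err) <= rt_window_min)
    if (!length(hit)) next
    best <- hit[which.min(abs(err_ppm[hit]))]
    out$name[i] <- library$name[best]
    out$mass_error_ppm[i] <- err_ppm[best]
    out$rt_error_min[i] <- rt_err[best]
    out$msi_level[i] <- 1L
  }
  out
}
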