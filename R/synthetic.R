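# Seeded synthetic-data generation: formula libraries, negative-mode feature
# tables with known ground truth, and stoichiometric cohort designs.

# Evaluate expr under a temporary RNG state; NULL seed = use current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Composition parameters for the random formula generator
#'
#' Heteroatom content of sampled formulas is controlled by small binomial
#' draws: `n = n_min + Binom(n_size, n_prob)` nitrogens,
#' `o = Binom(o_size, o_prob)` oxygens, a phosphorus block present with
#' probability `p_rate` carrying `1 + Binom(p_size, p_extra)` atoms, sulfur
#' present with probability `s_rate`, and an H/C ratio drawn uniformly from
#' `hc_range`. Raising `p_rate`/`p_extra` yields a phosphorus-enriched
#' library (lower C/P and N/P), which is how group-specific stoichiometric
#' shifts are planted.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of composition parameters.
#' @export
formula_composition <- function(...) {
  comp <- list(
    n_size = 4, n_prob = 0.3, n_min = 0,
    o_size = 10, o_prob = 0.3,
    p_rate = 0.3, p_size = 3, p_extra = 0.1,
    s_rate = 0.1,
    hc_range = c(0.8, 2.2)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(comp))
  if (length(bad)) stop("unknown composition fields: ", paste(bad, collapse = ", "))
  comp[names(dots)] <- dots
  comp
}

#' Sample random plausible CHNOPS formulas in a mass range
#'
#' Draws formulas by rejection sampling: heteroatom counts from
#' [formula_composition()], carbon/hydrogen filled in to hit a uniformly
#' drawn target mass with the hydrogen count parity-adjusted so the RDBE is
#' integer, then the same [element_ratio_rules()] used for candidate
#' filtering are applied - generator and filter are consistent by
#' construction. For very narrow ranges where rejection sampling starves, the
#' generator falls back to exhaustive enumeration of all valid formulas in
#' the range and samples from those.
#'
#' @param n Number of formulas (>= 1).
#' @param mass_range Neutral-mass interval in Da, within [15, 1000].
#' @param seed Optional integer seed; the same seed gives the same library.
#' @param composition A [formula_composition()].
#' @param config A [formula_config()] supplying rules and bounds.
#' @return data.frame: `formula` (Hill string), counts `c,h,n,o,p,s`, `mass`.
#' @export
sample_formula_library <- function(n, mass_range = c(85, 800), seed = NULL,
                                   composition = formula_composition(),
                                   config = formula_config()) {
  stopifnot(n >= 1, length(mass_range) == 2, mass_range[1] < mass_range[2],
            mass_range[1] >= 15, mass_range[2] <= 1000)
  with_seed(seed, {
    acc <- list()
    got <- 0
    tries <- 0
    while (got < n && tries < 60) {
      tries <- tries + 1
      m <- sample_formula_batch(max(4 * (n - got), 50), mass_range,
                                composition, config)
      if (nrow(m)) {
        acc[[tries]] <- m
        got <- got + nrow(m)
      }
    }
    if (got < n) {
      # narrow or awkward range: enumerate everything valid and sample
      all_valid <- exhaustive_formulas(mass_range, config)
      if (!nrow(all_valid)) {
        stop("no valid CHNOPS formula exists in [",
             mass_range[1], ", ", mass_range[2], "] Da under these rules")
      }
      idx <- sample.int(nrow(all_valid), n - got, replace = TRUE)
      acc[[length(acc) + 1]] <- as.matrix(all_valid[idx, ELEMENTS, drop = FALSE])
    }
    m <- do.call(rbind, acc)[seq_len(n), , drop = FALSE]
    data.frame(
      formula = apply(m, 1, function(r) format_formula(r[ELEMENTS])),
      m,
      mass = as.numeric(m %*% MONOISOTOPIC_MASS),
      stringsAsFactors = FALSE
    )
  })
}

# One vectorised rejection-sampling batch; returns a count matrix.
sample_formula_batch <- function(b, mass_range, comp, config) {
  target <- stats::runif(b, mass_range[1], mass_range[2])
  nn <- comp$n_min + stats::rbinom(b, comp$n_size, comp$n_prob)
  oo <- stats::rbinom(b, comp$o_size, comp$o_prob)
  pp <- stats::rbinom(b, 1, comp$p_rate) * (1 + stats::rbinom(b, comp$p_size, comp$p_extra))
  ss <- stats::rbinom(b, 1, comp$s_rate)
  het <- cbind(n = nn, o = oo, p = pp, s = ss) %*%
    MONOISOTOPIC_MASS[c("n", "o", "p", "s")]
  rem <- target - as.numeric(het)
  hc <- stats::runif(b, comp$hc_range[1], comp$hc_range[2])
  cc <- round(rem / (12 + MONOISOTOPIC_MASS[["h"]] * hc))
  hh <- round((rem - 12 * cc) / MONOISOTOPIC_MASS[["h"]])
  # force integer RDBE: (h + n + p) must be even
  odd <- (hh + nn + pp) %% 2 == 1
  hh[odd] <- hh[odd] - 1
  hh[hh < 0] <- hh[hh < 0] + 2
  m <- cbind(c = cc, h = hh, n = nn, o = oo, p = pp, s = ss)
  ok <- cc >= 1 & hh >= 0
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) return(m)
  within_bounds <- colSums(t(m) <= config$bounds[ELEMENTS]) == 6
  mass <- as.numeric(m %*% MONOISOTOPIC_MASS)
  keep <- within_bounds & mass >= mass_range[1] & mass <= mass_range[2] &
    rules_matrix(m, config)$pass
  m[keep, , drop = FALSE]
}

# Exhaustive enumeration of all rule-passing formulas in a (narrow) neutral
# mass range. Cost grows with range width; capped to stay a fallback.
exhaustive_formulas <- function(mass_range, config = formula_config()) {
  stopifnot(diff(mass_range) <= 25)
  grid <- nops_grid(config$bounds)
  keep <- grid$mass <= mass_range[2]
  gmass <- grid$mass[keep]
  gcounts <- grid$counts[keep, , drop = FALSE]
  mh <- MONOISOTOPIC_MASS[["h"]]
  rows <- list()
  for (cc in config$min_c:config$bounds[["c"]]) {
    rem_lo <- mass_range[1] - gmass - 12 * cc
    rem_hi <- mass_range[2] - gmass - 12 * cc
    hmin <- pmax(0, ceiling(rem_lo / mh - 1e-9))
    hmax <- pmin(config$bounds[["h"]], floor(rem_hi / mh + 1e-9))
    ok <- which(hmax >= hmin)
    if (!length(ok)) {
      if (all(rem_hi < 0)) break
      next
    }
    reps <- hmax[ok] - hmin[ok] + 1
    idx <- rep(ok, reps)
    h <- unlist(lapply(seq_along(ok), function(i) hmin[ok[i]]:hmax[ok[i]]))
    rows[[length(rows) + 1]] <- cbind(c = cc, h = h, gcounts[idx, , drop = FALSE])
  }
  m <- do.call(rbind, rows)
  if (is.null(m) || !nrow(m)) {
    return(data.frame(formula = character(), stringsAsFactors = FALSE))
  }
  m <- m[, ELEMENTS, drop = FALSE]
  m <- m[rules_matrix(m, config)$pass, , drop = FALSE]
  if (!nrow(m)) return(data.frame(formula = character(), stringsAsFactors = FALSE))
  data.frame(
    formula = apply(m, 1, function(r) format_formula(r[ELEMENTS])),
    m,
    mass = as.numeric(m %*% MONOISOTOPIC_MASS),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic study design
#'
#' Mirrors the sampled field study: six land-management groups with four
#' biological samples each, water blanks, 30 mg sample masses and a seeded
#' randomised injection order.
#'
#' @param groups Group names; the first is conventionally the reference.
#' @param n_per_group Samples per group (>= 2).
#' @param n_blanks Number of water blanks.
#' @param reference Reference group name (default `groups[1]`).
#' @param mass_mg Sample mass in mg (default 30).
#' @param seed Optional seed for the injection-order permutation.
#' @return A [study_design()].
#' @export
synthetic_design <- function(groups = c("pasture", "conventional_cultivation",
                                        "organic_cultivation", "hardwood_forest",
                                        "white_pine", "tulip_poplar"),
                             n_per_group = 4, n_blanks = 2,
                             reference = groups[1], mass_mg = 30, seed = NULL) {
  stopifnot(length(groups) >= 2, n_per_group >= 2, n_blanks >= 0)
  ids <- c(
    unlist(lapply(groups, function(g) paste0(g, "_", seq_len(n_per_group)))),
    if (n_blanks > 0) paste0("blank_", seq_len(n_blanks))
  )
  grp <- c(rep(groups, each = n_per_group), rep("blank", n_blanks))
  blank <- c(rep(FALSE, length(groups) * n_per_group), rep(TRUE, n_blanks))
  ord <- with_seed(seed, sample.int(length(ids)))
  study_design(ids, grp, blank, reference,
               mass_mg = ifelse(blank, NA_real_, mass_mg),
               injection_order = ord)
}

#' Simulate a negative-mode LC-MS feature table with known truth
#'
#' Emulates the instrument output the pipeline consumes: each library formula
#' becomes one `[M-H]-` feature whose recorded m/z is
#' `(true mass - proton mass) * (1 + ppm_error * 1e-6)` with the ppm error
#' drawn from a Gaussian truncated at +/- 3 sigma; intensities are log-normal
#' around a per-feature baseline with per-group log2 effects; retention times
#' respect the acquisition scan windows (m/z 85-800 before 9 min, 110-1000
#' after); water blanks carry a low-level contaminant subset and a small
#' "pure background" subset (features no stronger in samples than in blanks,
#' so the 3x blank rule removes them); and two spiked internal-standard
#' features (phenylalanine- and tryptophan-like) are present in every
#' non-blank sample at a target CV.
#'
#' @param design A [study_design()] with >= 2 non-blank groups, >= 2 samples
#'   per group.
#' @param library Formula library from [sample_formula_library()] (or any
#'   data.frame with count columns `c,h,n,o,p,s`).
#' @param effects `NULL`, or a named list mapping group name to a log2
#'   intensity effect (scalar, or one value per feature).
#' @param noise_sdlog Log-scale intensity noise sigma (>= 0; 0 gives
#'   noise-free intensities).
#' @param mass_error_ppm_sd Gaussian ppm-error sigma (default 0.5, truncated
#'   at 3 sigma; 0 gives exact masses).
#' @param blank_fraction Fraction of features present in blanks at low level.
#' @param blank_level Blank contaminant level relative to the feature median.
#' @param background_fraction Fraction of features that are pure background
#'   (blank signal comparable to sample signal; removed by the 3x rule).
#' @param internal_standards Add the two spiked standards (default TRUE).
#' @param is_cv_pct Target internal-standard CV in percent.
#' @param base_meanlog,base_sdlog Log-normal baseline of feature intensities.
#' @param seed Optional integer seed; fully determines the output.
#' @return List with `table` ([feature_table()]), `design` (with the
#'   internal-standard ids attached) and `truth` (data.frame: feature id,
#'   Hill formula, true mass, applied ppm error, roles, per-group log2
#'   effects as attribute `effects`).
#' @export
simulate_feature_table <- function(design, library, effects = NULL,
                                   noise_sdlog = 0.3, mass_error_ppm_sd = 0.5,
                                   blank_fraction = 0.2, blank_level = 0.1,
                                   background_fraction = 0.05,
                                   internal_standards = TRUE, is_cv_pct = 5,
                                   base_meanlog = log(1e6), base_sdlog = 1,
                                   seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            noise_sdlog >= 0, mass_error_ppm_sd >= 0,
            blank_fraction >= 0, blank_fraction <= 1,
            background_fraction >= 0, blank_fraction + background_fraction <= 1)
  groups <- unique(design$group[!design$is_blank])
  if (length(groups) < 2) stop("design needs at least two non-blank groups")
  tab_n <- table(design$group[!design$is_blank])
  if (any(tab_n < 2)) {
    stop("every group needs >= 2 samples; short: ",
         paste(names(tab_n)[tab_n < 2], collapse = ", "))
  }
  counts <- as.matrix(library[, ELEMENTS, drop = FALSE])
  nf <- nrow(counts)
  eff <- matrix(0, nf, length(groups), dimnames = list(NULL, groups))
  if (!is.null(effects)) {
    stopifnot(is.list(effects), all(names(effects) %in% groups))
    for (g in names(effects)) eff[, g] <- rep_len(effects[[g]], nf)
  }

  with_seed(seed, {
    true_mass <- as.numeric(counts %*% MONOISOTOPIC_MASS)
    ppm_err <- rtruncnorm(nf, mass_error_ppm_sd, 3)
    mz <- (true_mass - PROTON_MASS) * (1 + ppm_err * 1e-6)
    rt <- stats::runif(nf, 0.5, 24.5)
    rt[mz < 110] <- stats::runif(sum(mz < 110), 0.5, 8.9)
    rt[mz > 800] <- stats::runif(sum(mz > 800), 9.1, 24.5)

    meanlog <- stats::rnorm(nf, base_meanlog, base_sdlog)
    ns <- nrow(design)
    inten <- matrix(0, nf, ns, dimnames = list(NULL, design$sample_id))
    for (j in seq_len(ns)) {
      if (design$is_blank[j]) next
      g <- design$group[j]
      inten[, j] <- exp(meanlog + log(2) * eff[, g] +
                          stats::rnorm(nf, 0, noise_sdlog))
    }

    role <- rep("signal", nf)
    n_contam <- round(blank_fraction * nf)
    n_bg <- round(background_fraction * nf)
    pick <- sample.int(nf, n_contam + n_bg)
    contam <- pick[seq_len(n_contam)]
    bg <- setdiff(pick, contam)
    role[contam] <- "blank_contaminant"
    role[bg] <- "background"
    blanks <- which(design$is_blank)
    for (j in blanks) {
      inten[contam, j] <- blank_level * exp(meanlog[contam] +
                                              stats::rnorm(n_contam, 0, noise_sdlog))
      inten[bg, j] <- exp(meanlog[bg] + stats::rnorm(n_bg, 0, noise_sdlog))
    }
    # background features carry no group signal beyond baseline
    for (j in which(!design$is_blank)) {
      inten[bg, j] <- exp(meanlog[bg] + stats::rnorm(n_bg, 0, noise_sdlog))
    }

    ids <- sprintf("F%04d", seq_len(nf))
    feats <- data.frame(feature_id = ids, mz = mz, rt_min = rt,
                        stringsAsFactors = FALSE)
    truth <- data.frame(
      feature_id = ids,
      formula = apply(counts, 1, function(r) format_formula(r[ELEMENTS])),
      true_mass = true_mass, mz_error_ppm = ppm_err, role = role,
      stringsAsFactors = FALSE
    )

    is_ids <- character()
    if (internal_standards) {
      is_def <- data.frame(
        feature_id = c("IS_phenylalanine", "IS_tryptophan"),
        formula = c("C9H11NO2", "C11H12N2O2"),
        rt_min = c(9.5, 11.0), stringsAsFactors = FALSE
      )
      sdlog_is <- sqrt(log(1 + (is_cv_pct / 100)^2))
      is_mass <- vapply(is_def$formula, monoisotopic_mass, numeric(1))
      is_ppm <- rtruncnorm(2, mass_error_ppm_sd, 3)
      is_mz <- (is_mass - PROTON_MASS) * (1 + is_ppm * 1e-6)
      is_int <- matrix(0, 2, ns, dimnames = list(NULL, design$sample_id))
      nb <- which(!design$is_blank)
      is_int[, nb] <- exp(matrix(stats::rnorm(2 * length(nb), log(5e6), sdlog_is),
                                 2, length(nb)))
      feats <- rbind(feats, data.frame(feature_id = is_def$feature_id,
                                       mz = is_mz, rt_min = is_def$rt_min))
      inten <- rbind(inten, is_int)
      truth <- rbind(truth, data.frame(
        feature_id = is_def$feature_id, formula = is_def$formula,
        true_mass = is_mass, mz_error_ppm = is_ppm,
        role = "internal_standard", stringsAsFactors = FALSE
      ))
      is_ids <- is_def$feature_id
    }

    attr(truth, "effects") <- eff
    attr(truth, "noise_sdlog") <- noise_sdlog
    attr(truth, "seed") <- seed
    design2 <- design
    attr(design2, "internal_standards") <- is_ids
    list(table = feature_table(feats, inten), design = design2, truth = truth)
  })
}

# Gaussian truncated at +/- k*sd (resampling; exact for sd = 0).
rtruncnorm <- function(n, sd, k = 3) {
  if (sd == 0 || n == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > k * sd)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > k * sd]
  }
  x
}

#' Simulate a multi-group stoichiometric cohort
#'
#' Plants a group-level stoichiometric contrast by sampling each group's
#' feature formulas from composition-shifted libraries: the reference group's
#' library is enriched in phosphorus (more P-bearing formulas, higher P
#' counts), so its C/P and N/P ratios sit below the other groups'. With
#' `shift = FALSE` all groups share the common composition - the matched
#' no-effect control.
#'
#' @param n_per_group Formulas (features) per group.
#' @param groups Group names.
#' @param reference Reference group name.
#' @param mass_range Neutral-mass range of the sampled formulas.
#' @param shift Plant the phosphorus enrichment (default TRUE).
#' @param reference_composition,other_composition [formula_composition()]s
#'   used for the reference and the remaining groups.
#' @param seed Optional integer seed.
#' @return data.frame: `group`, `feature_id`, `formula`, counts, and ratio
#'   columns `cn`, `cp`, `np` (NA where the denominator count is zero).
#' @export
simulate_stoich_cohort <- function(n_per_group = 300,
                                   groups = c("pasture", "conventional_cultivation",
                                              "organic_cultivation", "hardwood_forest",
                                              "white_pine", "tulip_poplar"),
                                   reference = groups[1],
                                   mass_range = c(85, 500), shift = TRUE,
                                   reference_composition = formula_composition(
                                     n_min = 1, p_rate = 0.6, p_extra = 0.6
                                   ),
                                   other_composition = formula_composition(
                                     n_min = 1, p_rate = 0.3, p_extra = 0.05
                                   ),
                                   seed = NULL) {
  stopifnot(reference %in% groups, n_per_group >= 2)
  with_seed(seed, {
    out <- lapply(seq_along(groups), function(i) {
      g <- groups[i]
      comp <- if (shift && g == reference) reference_composition else other_composition
      lib <- sample_formula_library(n_per_group, mass_range, seed = NULL,
                                    composition = comp)
      data.frame(
        group = g,
        feature_id = sprintf("%s_F%04d", g, seq_len(n_per_group)),
        lib,
        cn = count_ratio(lib$c, lib$n),
        cp = count_ratio(lib$c, lib$p),
        np = count_ratio(lib$n, lib$p),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}
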