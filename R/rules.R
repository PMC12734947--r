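# Heuristic plausibility rules for candidate molecular formulas.

#' Default configuration for formula enumeration and filtering
#'
#' Collects every tunable used by [enumerate_candidates()] and
#' [element_ratio_rules()]:
#'
#' * `bounds`: element upper bounds for exhaustive enumeration. The defaults
#'   (C 70, H 120, N 20, O 30, P 8, S 8) cover organic compositions up to
#'   ~1000 Da while keeping enumeration fast.
#' * `min_c`: minimum carbon count (1 by default; set 0 to admit inorganic
#'   hydrides, in which case the carbon-based ratio checks are skipped).
#' * `ratio_limits`: permitted heteroatom-to-carbon ranges, the widely used
#'   "common range" heuristics: H/C in [0.2, 3.1], N/C <= 1.3, O/C <= 1.2,
#'   P/C <= 0.3, S/C <= 0.8.
#' * `p_valence`: phosphorus valence for RDBE (3 or 5).
#' * `ppm`: fixed ppm tolerance, or `NULL` to use the mass-dependent
#'   [ppm_tolerance()] (2 ppm < 500 Da, else 5 ppm).
#' * `observed_pattern`: observed A+1..A+3 isotope abundances (% of the
#'   monoisotopic peak) used to score candidates when no measured pattern is
#'   available; defaults to the conservative 5/5/5 placeholder.
#' * `abundance_error`: isotopic abundance error (%) used by the score.
#' * `min_isotope_score`: retention cutoff for the isotope match score.
#'
#' @param ... Named overrides of the defaults above (`bounds` and
#'   `ratio_limits` may be partial, e.g. `bounds = c(c = 20)`).
#' @return A list with class `formula_config`.
#' @export
formula_config <- function(...) {
  cfg <- list(
    bounds = c(c = 70, h = 120, n = 20, o = 30, p = 8, s = 8),
    min_c = 1,
    ratio_limits = c(
      hc_min = 0.2, hc_max = 3.1,
      nc_max = 1.3, oc_max = 1.2, pc_max = 0.3, sc_max = 0.8
    ),
    p_valence = 3,
    ppm = NULL,
    observed_pattern = c(5, 5, 5),
    abundance_error = 5,
    min_isotope_score = 30
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown formula_config fields: ", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    if (nm %in% c("bounds", "ratio_limits")) {
      repl <- dots[[nm]]
      stopifnot(!is.null(names(repl)), all(names(repl) %in% names(cfg[[nm]])))
      cfg[[nm]][names(repl)] <- repl
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(
    all(cfg$bounds >= 0), cfg$min_c >= 0,
    cfg$p_valence %in% c(3, 5),
    is.null(cfg$ppm) || cfg$ppm > 0,
    length(cfg$observed_pattern) == 3, all(cfg$observed_pattern >= 0),
    cfg$abundance_error >= 0,
    cfg$min_isotope_score >= 0, cfg$min_isotope_score <= 100
  )
  structure(cfg, class = "formula_config")
}

#' Element-ratio and RDBE plausibility rules
#'
#' A formula passes when it contains at least `min_c` carbons, its
#' heteroatom/carbon ratios fall inside the configured common ranges, and its
#' RDBE is non-negative and integer-valued (a valence requirement for intact
#' neutral molecules). The nitrogen-rule parity (odd/even nominal mass vs
#' nitrogen count) is reported for information but never used to reject,
#' since electron bookkeeping for deprotonated ions is ambiguous.
#'
#' @param f Element counts or formula string.
#' @param config A [formula_config()].
#' @return List with `pass` (logical), `checks` (named logicals for each
#'   rule), `rdbe`, and `nitrogen_rule_ok` (report-only).
#' @examples
#' element_ratio_rules("C6H12O6")$pass # TRUE
#' @export
element_ratio_rules <- function(f, config = formula_config()) {
  f <- as_counts(f)
  m <- matrix(f, nrow = 1, dimnames = list(NULL, ELEMENTS))
  det <- rules_matrix(m, config)
  list(
    pass = det$pass[1],
    checks = vapply(det$checks, `[`, logical(1), 1),
    rdbe = det$rdbe[1],
    nitrogen_rule_ok = det$nitrogen_rule_ok[1]
  )
}

# Vectorised rule evaluation over a count matrix; the single authoritative
# implementation behind element_ratio_rules() and enumerate_candidates().
rules_matrix <- function(m, config = formula_config()) {
  lim <- config$ratio_limits
  cc <- m[, "c"]
  r <- rdbe_matrix(m, config$p_valence)
  has_c <- cc >= max(1, config$min_c)
  # with min_c = 0 carbon-free formulas are admitted and ratio checks vacuous
  ratio_ok <- function(x, hi) ifelse(cc > 0, x / pmax(cc, 1) <= hi, TRUE)
  checks <- list(
    carbon = cc >= config$min_c & rowSums(m) >= 1,
    hc = ifelse(cc > 0,
      m[, "h"] / pmax(cc, 1) >= lim[["hc_min"]] & m[, "h"] / pmax(cc, 1) <= lim[["hc_max"]],
      TRUE
    ),
    nc = ratio_ok(m[, "n"], lim[["nc_max"]]),
    oc = ratio_ok(m[, "o"], lim[["oc_max"]]),
    pc = ratio_ok(m[, "p"], lim[["pc_max"]]),
    sc = ratio_ok(m[, "s"], lim[["sc_max"]]),
    rdbe_nonneg = r >= -1e-9,
    rdbe_integer = abs(r - round(r)) < 1e-9
  )
  pass <- Reduce(`&`, checks)
  # nitrogen rule on the neutral molecule: integer RDBE is equivalent, so an
  # even (H + N + P) sum; reported only.
  nr <- (m[, "h"] + m[, "n"] + m[, "p"]) %% 2 == 0
  list(pass = unname(pass), checks = checks, rdbe = unname(r),
       nitrogen_rule_ok = unname(nr))
}
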