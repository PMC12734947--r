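# Element constants and formula arithmetic for the CHNOPS universe.

#' @keywords internal
ELEMENTS <- c("c", "h", "n", "o", "p", "s")

# Monoisotopic (lightest stable isotope) masses, Da.
MONOISOTOPIC_MASS <- c(
  c = 12.0,
  h = 1.0078250319,
  n = 14.0030740052,
  o = 15.9949146221,
  p = 30.97376151,
  s = 31.97207069
)

# Proton mass used for the [M-H]- adduct; the electron mass is implicitly
# accounted for by using the proton (not hydrogen-atom) mass.
PROTON_MASS <- 1.007276466

#' Construct an element-count vector over C, H, N, O, P, S
#'
#' Element counts are the universal formula currency of the package: a named
#' numeric vector with entries `c, h, n, o, p, s`. Counts must be
#' non-negative; integers are required unless `fractional = TRUE` (composite
#' formulas average counts over candidates and are therefore rational).
#'
#' @param c,h,n,o,p,s Non-negative atom counts.
#' @param fractional Allow non-integer counts (used for composite formulas).
#' @return Named numeric vector of length 6.
#' @examples
#' element_counts(c = 6, h = 12, o = 6) # glucose
#' @export
element_counts <- function(c = 0, h = 0, n = 0, o = 0, p = 0, s = 0,
                           fractional = FALSE) {
  x <- c(c = unname(c), h = unname(h), n = unname(n), o = unname(o),
         p = unname(p), s = unname(s))
  if (anyNA(x) || any(x < 0)) {
    stop("element counts must be non-negative and non-missing")
  }
  if (!fractional && any(abs(x - round(x)) > 1e-9)) {
    stop("element counts must be integers (use fractional = TRUE for composites)")
  }
  if (sum(x) < 1) stop("a formula must contain at least one atom")
  x
}

#' Parse a molecular formula string into element counts
#'
#' Accepts Hill-order (or any-order) formula strings restricted to the
#' elements C, H, N, O, P and S, e.g. `"C6H12O6"` or `"H2O"`.
#'
#' @param formula Character scalar.
#' @return Named numeric vector as returned by [element_counts()].
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula string: ", formula)
  }
  out <- stats::setNames(numeric(6), ELEMENTS)
  for (tok in tokens) {
    sym <- tolower(gsub("[0-9]", "", tok))
    if (!sym %in% ELEMENTS) {
      stop("element '", sym, "' is outside the CHNOPS universe in: ", formula)
    }
    num <- gsub("[A-Za-z]", "", tok)
    out[sym] <- out[sym] + if (nzchar(num)) as.numeric(num) else 1
  }
  element_counts(out["c"], out["h"], out["n"], out["o"], out["p"], out["s"])
}

#' Format element counts as a Hill-order formula string
#'
#' Hill order: carbon first, hydrogen second, remaining elements
#' alphabetically (N, O, P, S). Elements with zero count are omitted; a count
#' of one is written without a number.
#'
#' @param f Element counts (integer-valued).
#' @return Character scalar.
#' @export
format_formula <- function(f) {
  f <- as_counts(f)
  if (any(abs(f - round(f)) > 1e-9)) {
    stop("only integer formulas can be formatted in Hill order")
  }
  f <- round(f)
  sym <- c(c = "C", h = "H", n = "N", o = "O", p = "P", s = "S")
  parts <- vapply(ELEMENTS, function(el) {
    k <- f[[el]]
    if (k == 0) "" else if (k == 1) sym[[el]] else paste0(sym[[el]], k)
  }, character(1))
  paste0(parts, collapse = "")
}

# Coerce a formula string or count vector to canonical counts.
as_counts <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f)) && all(ELEMENTS %in% names(f))) {
    return(f[ELEMENTS])
  }
  stop("expected a formula string or a named element-count vector")
}

#' Monoisotopic mass of a formula
#'
#' Sum of lightest-isotope atomic masses (1H, 12C, 14N, 16O, 31P, 32S).
#'
#' @param f Element counts or formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C6H12O6")
#' @export
monoisotopic_mass <- function(f) {
  f <- as_counts(f)
  sum(f * MONOISOTOPIC_MASS)
}

#' Convert between observed m/z and neutral monoisotopic mass
#'
#' For the deprotonated negative-mode ion `[M-H]-`:
#' `M = m/z + 1.007276466` (proton mass). `mz_from_neutral_mass()` is the
#' exact inverse.
#'
#' @param mz Observed m/z (Th).
#' @param mass Neutral monoisotopic mass (Da).
#' @param ion Adduct tag; only `"[M-H]-"` is supported.
#' @return Neutral mass (Da), or m/z (Th) for the inverse.
#' @export
neutral_mass_from_mz <- function(mz, ion = "[M-H]-") {
  check_adduct(ion)
  stopifnot(all(mz > 0))
  mz + PROTON_MASS
}

#' @rdname neutral_mass_from_mz
#' @export
mz_from_neutral_mass <- function(mass, ion = "[M-H]-") {
  check_adduct(ion)
  stopifnot(all(mass > PROTON_MASS))
  mass - PROTON_MASS
}

check_adduct <- function(ion) {
  # accept the unicode minus variants users paste from papers
  ok <- gsub("−", "-", ion) == "[M-H]-"
  if (!isTRUE(ok)) stop("unsupported adduct tag: ", ion, " (only [M-H]- is supported)")
  invisible(TRUE)
}

#' Mass-dependent ppm tolerance for formula assignment
#'
#' 2 ppm for masses below 500 Da and 5 ppm at or above 500 Da, matching
#' typical Orbitrap accuracy in untargeted work. The 500 Da boundary itself
#' falls in the 5 ppm regime.
#'
#' @param mass Neutral mass (Da).
#' @return Tolerance in ppm.
#' @export
ppm_tolerance <- function(mass) {
  stopifnot(all(mass > 0))
  ifelse(mass < 500, 2, 5)
}

#' Ring and double bond equivalents
#'
#' `RDBE = C - H/2 + (N + P)/2 + 1` with oxygen and sulfur divalent and
#' phosphorus trivalent (the default for most organics). Set
#' `p_valence = 5` for the pentavalent-phosphorus convention, under which
#' each P contributes 3/2 instead of 1/2.
#'
#' @param f Element counts or formula string.
#' @param p_valence Phosphorus valence, 3 (default) or 5.
#' @return RDBE (may be half-integer for ion-like compositions).
#' @examples
#' rdbe("C6H6") # benzene: 4
#' @export
rdbe <- function(f, p_valence = 3) {
  f <- as_counts(f)
  stopifnot(p_valence %in% c(3, 5))
  p_contrib <- if (p_valence == 3) 0.5 else 1.5
  unname(f[["c"]] - f[["h"]] / 2 + f[["n"]] / 2 + p_contrib * f[["p"]] + 1)
}

# Vectorised RDBE over a count matrix (columns c,h,n,o,p,s).
rdbe_matrix <- function(m, p_valence = 3) {
  p_contrib <- if (p_valence == 3) 0.5 else 1.5
  m[, "c"] - m[, "h"] / 2 + m[, "n"] / 2 + p_contrib * m[, "p"] + 1
}
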