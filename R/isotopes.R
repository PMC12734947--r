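# Theoretical isotope patterns and the isotope match score.

# Natural isotope abundances per element, indexed by nucleon offset from the
# lightest isotope (offset 0). Values sum to 1 per element; offsets beyond
# +3 only matter for 36S and are dropped by the truncation.
ISOTOPE_DIST <- list(
  c = c(0.9893, 0.0107),
  h = c(0.999885, 0.000115),
  n = c(0.99636, 0.00364),
  o = c(0.99757, 0.00038, 0.00205),
  p = c(1),
  s = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# Truncated polynomial product: distributions over nucleon offsets 0..max_k.
conv_trunc <- function(a, b, max_k = 3) {
  n <- max_k + 1
  a <- a[seq_len(min(length(a), n))]
  b <- b[seq_len(min(length(b), n))]
  out <- numeric(n)
  for (i in seq_along(a)) {
    j <- seq_len(min(length(b), n - i + 1))
    out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  }
  out
}

# dist^k by exponentiation-by-squaring, truncated after offset max_k.
poly_power <- function(dist, k, max_k = 3) {
  out <- c(1, numeric(max_k))
  base <- c(dist, numeric(max_k))[seq_len(max_k + 1)]
  while (k > 0) {
    if (k %% 2 == 1) out <- conv_trunc(out, base, max_k)
    base <- conv_trunc(base, base, max_k)
    k <- k %/% 2
  }
  out
}

#' Theoretical A+1..A+3 isotope pattern of a formula
#'
#' Relative abundances of the isotopologue peaks one to three nucleons above
#' the monoisotopic (A) peak, as percentages of the A peak. Computed by exact
#' polynomial convolution of the per-element natural isotope distributions
#' (e.g. 13C 1.07%, 18O 0.205%, 34S 4.25%), truncated after A+3.
#'
#' @param f Element counts or formula string.
#' @return Numeric vector `c(a1, a2, a3)` in percent of the A peak.
#' @examples
#' theoretical_isotope_pattern("C6H12O6")
#' @export
theoretical_isotope_pattern <- function(f) {
  f <- as_counts(f)
  if (any(abs(f - round(f)) > 1e-9)) stop("isotope patterns require integer formulas")
  p <- c(1, 0, 0, 0)
  for (el in ELEMENTS) {
    k <- round(f[[el]])
    if (k > 0) p <- conv_trunc(p, poly_power(ISOTOPE_DIST[[el]], k), 3)
  }
  if (p[1] <= 0) stop("degenerate isotope distribution")
  stats::setNames(100 * p[2:4] / p[1], c("a1", "a2", "a3"))
}

#' Isotope pattern match score
#'
#' Similarity between observed and theoretical relative A+1..A+3 abundances,
#' on a 0-100 scale. Each peak contributes
#' `max(0, 1 - |obs - theo| / (max(obs, theo) + abundance_error))`
#' and the score is 100 times the mean of the three peak terms. The score is
#' 100 exactly when the patterns agree on all peaks, decreases monotonically
#' in each absolute deviation, and the additive `abundance_error` keeps the
#' score tolerant when low-abundance peaks (or the 5/5/5 placeholder pattern
#' used in the absence of measured isotopes) are compared.
#'
#' @param observed,theoretical Length-3 numeric vectors, A+1..A+3 abundances
#'   in percent of the A peak.
#' @param abundance_error Isotopic abundance error in percentage points
#'   (default 5).
#' @return Score in [0, 100].
#' @examples
#' isotope_match_score(c(5, 5, 5), c(5, 5, 5)) # 100
#' @export
isotope_match_score <- function(observed, theoretical, abundance_error = 5) {
  stopifnot(
    length(observed) == 3, length(theoretical) == 3,
    all(observed >= 0), all(theoretical >= 0), abundance_error >= 0
  )
  denom <- pmax(observed, theoretical) + abundance_error
  term <- pmax(0, 1 - abs(observed - theoretical) / denom)
  term[denom == 0] <- 1 # both zero and no tolerance: perfect agreement
  100 * mean(term)
}
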