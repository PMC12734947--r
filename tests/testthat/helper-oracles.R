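# Independent oracle implementations used to cross-check the package. These
# deliberately share no code with the package: masses are re-typed, the
# isotope convolution walks atom by atom, the rule arithmetic is rewritten,
# and the enumerator is a naive scan over a full six-element grid.

ORACLE_MASS <- c(c = 12.0, h = 1.0078250319, n = 14.0030740052,
                 o = 15.9949146221, p = 30.97376151, s = 31.97207069)
ORACLE_PROTON <- 1.007276466

oracle_mass <- function(counts) {
  sum(counts[c("c", "h", "n", "o", "p", "s")] *
        ORACLE_MASS[c("c", "h", "n", "o", "p", "s")])
}

# Atom-by-atom convolution of the isotope distribution, truncated at A+3.
oracle_isotope_pattern <- function(counts) {
  dists <- list(
    c = c(0.9893, 0.0107),
    h = c(0.999885, 0.000115),
    n = c(0.99636, 0.00364),
    o = c(0.99757, 0.00038, 0.00205),
    p = c(1),
    s = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  pat <- c(1, 0, 0, 0)
  for (el in names(dists)) {
    k <- counts[[el]]
    if (is.na(k) || k == 0) next
    d <- dists[[el]]
    for (rep in seq_len(k)) {
      new <- numeric(4)
      for (i in 1:4) {
        for (j in seq_along(d)) {
          if (i + j - 1 <= 4) new[i + j - 1] <- new[i + j - 1] + pat[i] * d[j]
        }
      }
      pat <- new
    }
  }
  100 * pat[2:4] / pat[1]
}

oracle_score <- function(obs, theo, err = 5) {
  s <- 0
  for (k in 1:3) {
    den <- max(obs[k], theo[k]) + err
    s <- s + if (den == 0) 1 else max(0, 1 - abs(obs[k] - theo[k]) / den)
  }
  100 * s / 3
}

# Rewritten plausibility rules (default limits, trivalent P, integer RDBE).
oracle_rules_pass <- function(cc, hh, nn, oo, pp, ss) {
  r <- cc - hh / 2 + (nn + pp) / 2 + 1
  cc >= 1 &
    hh / cc >= 0.2 & hh / cc <= 3.1 &
    nn / cc <= 1.3 & oo / cc <= 1.2 & pp / cc <= 0.3 & ss / cc <= 0.8 &
    r >= 0 & abs(r - round(r)) < 1e-9
}

# Bounds shared by the oracle and the package config in equivalence tests.
ORACLE_BOUNDS <- c(c = 18, h = 36, n = 8, o = 12, p = 3, s = 3)

# Full naive grid over all six elements (built once per test run).
oracle_grid <- local({
  grid <- NULL
  function() {
    if (!is.null(grid)) return(grid)
    g <- expand.grid(
      c = 1:ORACLE_BOUNDS[["c"]], h = 0:ORACLE_BOUNDS[["h"]],
      n = 0:ORACLE_BOUNDS[["n"]], o = 0:ORACLE_BOUNDS[["o"]],
      p = 0:ORACLE_BOUNDS[["p"]], s = 0:ORACLE_BOUNDS[["s"]],
      KEEP.OUT.ATTRS = FALSE
    )
    g$mass <- g$c * ORACLE_MASS[["c"]] + g$h * ORACLE_MASS[["h"]] +
      g$n * ORACLE_MASS[["n"]] + g$o * ORACLE_MASS[["o"]] +
      g$p * ORACLE_MASS[["p"]] + g$s * ORACLE_MASS[["s"]]
    pass <- oracle_rules_pass(g$c, g$h, g$n, g$o, g$p, g$s)
    grid <<- g[pass & g$mass <= 320, , drop = FALSE]
    grid
  }
})

# Naive brute-force enumeration with the default filters: every rule-passing
# grid formula whose [M-H]- m/z is within tol ppm, scored against the 5/5/5
# placeholder with the 30% cutoff. Returns sorted Hill formula strings.
oracle_enumerate <- function(mz, tol_ppm = 2, min_score = 30) {
  g <- oracle_grid()
  theo_mz <- g$mass - ORACLE_PROTON
  ppm <- (mz - theo_mz) / theo_mz * 1e6
  hits <- g[abs(ppm) <= tol_ppm + 1e-12, , drop = FALSE]
  if (!nrow(hits)) return(character())
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    theo <- oracle_isotope_pattern(hits[i, c("c", "h", "n", "o", "p", "s")])
    oracle_score(c(5, 5, 5), theo) >= min_score
  }, logical(1))
  hits <- hits[keep, , drop = FALSE]
  out <- vapply(seq_len(nrow(hits)), function(i) {
    hill <- ""
    sym <- c(c = "C", h = "H", n = "N", o = "O", p = "P", s = "S")
    for (el in c("c", "h", "n", "o", "p", "s")) {
      k <- hits[i, el]
      if (k == 1) hill <- paste0(hill, sym[[el]])
      else if (k > 1) hill <- paste0(hill, sym[[el]], k)
    }
    hill
  }, character(1))
  sort(out)
}
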