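# Small in-code fixtures shared across test files.

# The five-feature blank-rule toy: non-blank/blank mean pairs
# (400/100, 300/100, 50/0, 10/100, 90/30); under the strict >3x mean rule
# exactly features 1 and 3 survive.
toy_blank_table <- function() {
  sample_means <- c(400, 300, 50, 10, 90)
  blank_means <- c(100, 100, 0, 100, 30)
  inten <- cbind(
    s1 = sample_means, s2 = sample_means,
    b1 = blank_means, b2 = blank_means
  )
  feats <- data.frame(
    feature_id = paste0("f", 1:5),
    mz = c(100, 150, 200, 250, 300) + 0.5,
    rt_min = 1:5
  )
  list(
    table = feature_table(feats, inten),
    design = study_design(
      c("s1", "s2", "b1", "b2"),
      c("grass", "grass", "blank", "blank"),
      c(FALSE, FALSE, TRUE, TRUE),
      reference = "grass",
      mass_mg = c(30, 30, NA, NA)
    )
  )
}

# Six-group cohort with planted between-group separation on every variable:
# group means ~ N(0, between_sd), within-group noise ~ N(0, 1), so the
# between/within variance ratio is between_sd^2.
separated_cohort <- function(seed, n_per_group = 4, n_groups = 6, p = 150,
                             between_sd = 3) {
  set.seed(seed)
  y <- rep(paste0("g", seq_len(n_groups)), each = n_per_group)
  mu <- matrix(stats::rnorm(n_groups * p, 0, between_sd), n_groups, p)
  X <- mu[as.integer(factor(y)), ] + matrix(stats::rnorm(length(y) * p),
                                            length(y), p)
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, y = y)
}

# Random candidate data.frames (1-3 rows) for composite-formula properties.
random_candidates <- function(n_rows, shared_n = NULL, shared_p = NULL) {
  data.frame(
    c = sample(1:20, n_rows, replace = TRUE),
    h = sample(0:30, n_rows, replace = TRUE),
    n = if (is.null(shared_n)) sample(0:5, n_rows, replace = TRUE) else shared_n,
    o = sample(0:10, n_rows, replace = TRUE),
    p = if (is.null(shared_p)) sample(0:3, n_rows, replace = TRUE) else shared_p,
    s = sample(0:2, n_rows, replace = TRUE)
  )
}

# Minimal candidate data.frame with tied scores and ppm errors, for ranking
# tiebreak tests.
candidates_from_formulas <- function(formulas) {
  counts <- t(vapply(formulas, parse_formula, numeric(6)))
  data.frame(
    formula = formulas,
    counts,
    theoretical_mass = apply(counts, 1, monoisotopic_mass),
    theoretical_mz = apply(counts, 1, monoisotopic_mass) - 1.007276466,
    mz_error_ppm = 0.5,
    rdbe = apply(counts, 1, rdbe),
    nitrogen_rule_ok = TRUE,
    isotope_score = 80,
    rank = NA_integer_,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
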