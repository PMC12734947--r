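# QA/QC gates: blank-based feature retention, internal-standard CV,
# sample-mass normalisation and the injection-order drift diagnostic.

#' Blank-based feature retention
#'
#' Retains exactly the features whose mean intensity across non-blank samples
#' is strictly greater than `ratio` times the blank signal (mean across blank
#' samples by default, maximum with `blank_stat = "max"`). Features absent
#' from the blanks (blank signal 0) are retained whenever their non-blank
#' mean is positive; feature order is preserved. The default strict `> 3x`
#' reading is the conservative interpretation of an "at least >3x" rule.
#'
#' @param table A [feature_table()].
#' @param design A [study_design()] with at least one blank sample.
#' @param ratio Retention ratio (> 0; default 3).
#' @param blank_stat `"mean"` (default) or `"max"` blank signal.
#' @return The filtered [feature_table()], with attribute `qc_log`
#'   (features in/out).
#' @export
blank_filter <- function(table, design, ratio = 3, blank_stat = c("mean", "max")) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "study_design"),
            ratio >= 0)
  blank_stat <- match.arg(blank_stat)
  blanks <- design$sample_id[design$is_blank]
  if (!length(blanks)) {
    stop("no blank samples in the design; skip blank filtering instead")
  }
  samples <- design$sample_id[!design$is_blank]
  stopifnot(all(c(blanks, samples) %in% table$samples))
  bm <- if (blank_stat == "mean") {
    rowMeans(table$intensities[, blanks, drop = FALSE])
  } else {
    apply(table$intensities[, blanks, drop = FALSE], 1, max)
  }
  sm <- rowMeans(table$intensities[, samples, drop = FALSE])
  keep <- sm > ratio * bm
  out <- subset_features(table, which(keep))
  attr(out, "qc_log") <- data.frame(
    stage = "blank_filter", features_in = nrow(table$features),
    features_out = nrow(out$features), stringsAsFactors = FALSE
  )
  out
}

#' Internal-standard coefficient of variation
#'
#' CV (%) of a spiked internal-standard feature across non-blank samples:
#' `100 * sd / mean`, with a pass flag against a configurable acceptance
#' threshold.
#'
#' @param table A [feature_table()].
#' @param feature_id Feature id of the internal standard.
#' @param design A [study_design()] with >= 2 non-blank samples.
#' @param threshold Acceptance threshold in percent (default 30).
#' @return List: `cv_pct`, `pass`, `n`, `mean`, `sd`.
#' @export
internal_standard_cv <- function(table, feature_id, design, threshold = 30) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "study_design"))
  if (!feature_id %in% table$features$feature_id) {
    stop("internal-standard feature '", feature_id, "' not present in the table")
  }
  samples <- design$sample_id[!design$is_blank]
  if (length(samples) < 2) stop("CV needs >= 2 non-blank samples")
  x <- table$intensities[feature_id, samples]
  m <- mean(x)
  if (m == 0) stop("internal standard '", feature_id, "' has zero mean intensity; CV undefined")
  cv <- 100 * stats::sd(x) / m
  list(cv_pct = cv, pass = cv <= threshold, n = length(x), mean = m,
       sd = stats::sd(x))
}

#' Normalise intensities by sample mass
#'
#' Divides every non-blank sample's intensity column by its sample mass (mg).
#' Blanks are left untouched by default or dropped with
#' `drop_blanks = TRUE`.
#'
#' @param table A [feature_table()].
#' @param design A [study_design()] carrying `mass_mg` for all non-blank
#'   samples.
#' @param drop_blanks Remove blank columns from the result.
#' @return The normalised [feature_table()].
#' @export
mass_normalize <- function(table, design, drop_blanks = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "study_design"))
  nb <- design[!design$is_blank, , drop = FALSE]
  missing_mass <- nb$sample_id[is.na(nb$mass_mg) | nb$mass_mg <= 0]
  if (length(missing_mass)) {
    stop("missing or non-positive sample mass for: ",
         paste(missing_mass, collapse = ", "))
  }
  inten <- table$intensities
  inten[, nb$sample_id] <- sweep(inten[, nb$sample_id, drop = FALSE], 2,
                                 nb$mass_mg, `/`)
  if (drop_blanks) {
    keep <- setdiff(colnames(inten), design$sample_id[design$is_blank])
    inten <- inten[, keep, drop = FALSE]
  }
  feature_table(table$features, inten)
}

#' Injection-order drift diagnostic (report only)
#'
#' Regresses log internal-standard intensity on injection order and reports
#' the slope and its p-value. Purely diagnostic: no correction is applied,
#' since drift/batch correction is deliberately out of scope for small runs.
#'
#' @param table A [feature_table()].
#' @param feature_id Internal-standard feature id.
#' @param design A [study_design()] with injection order recorded.
#' @return data.frame: `feature_id`, `slope`, `p_value`, `n`.
#' @export
injection_order_drift <- function(table, feature_id, design) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "study_design"))
  nb <- design[!design$is_blank & !is.na(design$injection_order), , drop = FALSE]
  if (nrow(nb) < 3) stop("drift check needs >= 3 samples with injection order")
  y <- log(table$intensities[feature_id, nb$sample_id])
  fit <- stats::lm(y ~ nb$injection_order)
  sm <- summary(fit)$coefficients
  data.frame(feature_id = feature_id, slope = sm[2, 1], p_value = sm[2, 4],
             n = nrow(nb), stringsAsFactors = FALSE)
}
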