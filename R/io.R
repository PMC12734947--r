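# Containers and CSV interchange: feature tables, study designs, compound
# libraries, and the plain-text pipeline configuration.

#' Construct a feature table
#'
#' The pipeline's central container: per-feature m/z and retention time plus
#' a non-negative intensity matrix (features x samples, arbitrary units).
#'
#' @param features data.frame with columns `feature_id` (unique), `mz` (> 0)
#'   and `rt_min` (>= 0).
#' @param intensities Numeric matrix, one row per feature (rownames =
#'   feature ids), one column per sample (colnames = sample ids).
#' @return Object of class `feature_table`: list with `features`, `samples`,
#'   `intensities`.
#' @export
feature_table <- function(features, intensities) {
  stopifnot(
    is.data.frame(features),
    all(c("feature_id", "mz", "rt_min") %in% names(features)),
    is.matrix(intensities), is.numeric(intensities),
    nrow(intensities) == nrow(features)
  )
  features$feature_id <- as.character(features$feature_id)
  dup <- features$feature_id[duplicated(features$feature_id)]
  if (length(dup)) stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(features$mz) || any(features$mz <= 0)) stop("m/z values must be positive")
  if (anyNA(features$rt_min) || any(features$rt_min < 0)) stop("retention times must be >= 0")
  if (anyNA(intensities) || any(intensities < 0)) stop("intensities must be non-negative")
  if (is.null(colnames(intensities))) stop("intensity matrix needs sample ids as colnames")
  rownames(intensities) <- features$feature_id
  features <- features[c("feature_id", "mz", "rt_min")]
  rownames(features) <- NULL
  structure(
    list(features = features,
         samples = colnames(intensities),
         intensities = intensities),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$features), "features x",
      length(x$samples), "samples\n")
  cat("  m/z range:", format(range(x$features$mz), digits = 7), "\n")
  cat("  RT range (min):", format(range(x$features$rt_min), digits = 4), "\n")
  invisible(x)
}

# Subset a feature table by feature index or id, preserving order.
subset_features <- function(table, idx) {
  feature_table(table$features[idx, , drop = FALSE],
                table$intensities[idx, , drop = FALSE])
}

#' Construct a study design
#'
#' Maps samples to groups and carries the QC metadata: blank flags, sample
#' masses (mg, used by [mass_normalize()]), injection order and the reference
#' group for pairwise statistics.
#'
#' @param sample_id Unique sample ids (must match feature-table columns).
#' @param group Group label per sample; blanks conventionally "blank".
#' @param is_blank Logical per sample.
#' @param reference Name of the reference group (must be a non-blank group).
#' @param mass_mg Optional sample masses in mg.
#' @param injection_order Optional integer injection order.
#' @param internal_standards Optional character vector of feature ids spiked
#'   at constant concentration (e.g. phenylalanine/tryptophan standards).
#' @return data.frame of class `study_design` with attributes `reference` and
#'   `internal_standards`.
#' @export
study_design <- function(sample_id, group, is_blank = FALSE, reference,
                         mass_mg = NA_real_, injection_order = NA_integer_,
                         internal_standards = character()) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    group = as.character(group),
    is_blank = rep_len(as.logical(is_blank), length(sample_id)),
    mass_mg = rep_len(as.numeric(mass_mg), length(sample_id)),
    injection_order = rep_len(as.integer(injection_order), length(sample_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$sample_id)) stop("sample ids must be unique")
  if (!reference %in% d$group[!d$is_blank]) {
    stop("reference group '", reference, "' has no non-blank samples")
  }
  structure(d, class = c("study_design", "data.frame"),
            reference = reference, internal_standards = internal_standards)
}

reference_group <- function(design) attr(design, "reference")

#' Read / write the feature-table CSV
#'
#' Schema: `feature_id, mz, rt_min`, then one numeric column per sample.
#' Lines starting with `#` are provenance comments and are skipped on read.
#' Write-then-read is the identity.
#'
#' @param path File path.
#' @param table A [feature_table()].
#' @param comment Optional character vector written as leading `#` lines.
#' @return `read_feature_table()` returns a [feature_table()].
#' @export
read_feature_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(df), need)
  if (!length(sample_cols)) stop("feature table has no sample columns")
  for (cl in c("mz", "rt_min", sample_cols)) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", cl, "'",
           if (length(bad)) paste0(" at row ", bad[1]) else "")
    }
  }
  neg <- which(as.matrix(df[sample_cols]) < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative intensity for feature '", df$feature_id[neg[1, 1]],
         "' in sample '", sample_cols[neg[1, 2]], "'")
  }
  feature_table(df[need], as.matrix(df[sample_cols]))
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path, comment = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$features, as.data.frame(table$intensities, optional = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the study-design CSV
#'
#' Columns `sample_id, group, is_blank, mass_mg, injection_order`; the
#' reference group and internal-standard feature ids travel as `#`-comment
#' header lines so the file round-trips losslessly.
#'
#' @param design A [study_design()].
#' @param path File path.
#' @export
write_design <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# reference=", reference_group(design)), con)
  is_ids <- attr(design, "internal_standards")
  if (length(is_ids)) {
    writeLines(paste0("# internal_standards=", paste(is_ids, collapse = ";")), con)
  }
  utils::write.csv(as.data.frame(design), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  stopifnot(file.exists(path))
  header <- grep("^#", readLines(path, n = 10), value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, "="), header, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ref <- get_field("reference")
  if (is.null(ref)) stop("design file lacks a '# reference=' header line")
  is_ids <- get_field("internal_standards")
  study_design(df$sample_id, df$group, df$is_blank, ref,
               df$mass_mg, df$injection_order,
               if (is.null(is_ids)) character() else strsplit(is_ids, ";")[[1]])
}

#' Read a known-compound library CSV
#'
#' Columns: `name`, `rt_min`, and `mass` (neutral monoisotopic Da) and/or
#' `formula` (Hill string; the mass is computed when absent).
#'
#' @param path File path.
#' @return data.frame with `name`, `formula`, `mass`, `rt_min`.
#' @export
read_compound_library <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "rt_min") %in% names(df))) {
    stop("library needs 'name' and 'rt_min' columns")
  }
  if (is.null(df$mass)) df$mass <- NA_real_
  if (is.null(df$formula)) df$formula <- NA_character_
  need <- is.na(df$mass)
  if (any(need & is.na(df$formula))) {
    stop("library entries need a mass or a formula: ",
         paste(df$name[need & is.na(df$formula)], collapse = ", "))
  }
  df$mass[need] <- vapply(df$formula[need], function(f) monoisotopic_mass(f), numeric(1))
  df[c("name", "formula", "mass", "rt_min")]
}
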