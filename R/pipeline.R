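# End-to-end pipeline driver: configuration, provenance, stage ordering and
# report-bundle output.

#' Pipeline configuration
#'
#' Collects every pipeline tunable with validated defaults. Paths may be NULL
#' when `simulate = TRUE`, in which case a seeded synthetic study is
#' generated in place of input files.
#'
#' @param feature_table,design,library Input CSV paths (library optional).
#' @param out_dir Output directory for the report bundle.
#' @param simulate Generate synthetic inputs instead of reading files.
#' @param n_features Synthetic library size when simulating.
#' @param blank_filter Apply the blank-retention gate (default TRUE).
#' @param blank_ratio Blank-retention ratio (default 3).
#' @param blank_stat Blank signal summary, `"mean"` or `"max"`.
#' @param is_cv_limit Internal-standard CV acceptance threshold (%).
#' @param ppm Fixed enumeration tolerance in ppm, or NA for the
#'   mass-dependent default (2 ppm below 500 Da, 5 ppm above).
#' @param min_isotope_score Isotope match score cutoff (default 30).
#' @param max_candidates Candidates averaged per composite (default 3).
#' @param composite_mode `"average-counts"` or `"average-ratios"`.
#' @param iqr_drop_fraction IQR prefilter drop fraction (default 0.25).
#' @param presence_fraction Group-presence threshold for ratio distributions.
#' @param alpha Significance level (default 0.05).
#' @param min_abs_log2fc Volcano fold-change gate (default 1).
#' @param p_adjust `"BH"` or `"none"` (feature-level tests; ratio-level
#'   pairwise tests are reported unadjusted).
#' @param n_components PLS-DA components (default 2).
#' @param folds Cross-validation folds (default 5).
#' @param seed Master seed; per-stage seeds derive from it and are logged.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_table = NULL, design = NULL, library = NULL,
                            out_dir = "ms1stoich_out", simulate = FALSE,
                            n_features = 150,
                            blank_filter = TRUE, blank_ratio = 3,
                            blank_stat = "mean", is_cv_limit = 30,
                            ppm = NA_real_, min_isotope_score = 30,
                            max_candidates = 3,
                            composite_mode = "average-counts",
                            iqr_drop_fraction = 0.25, presence_fraction = 0.5,
                            alpha = 0.05, min_abs_log2fc = 1, p_adjust = "BH",
                            n_components = 2, folds = 5, seed = 0) {
  cfg <- list(
    feature_table = feature_table, design = design, library = library,
    out_dir = out_dir, simulate = simulate, n_features = n_features,
    blank_filter = blank_filter, blank_ratio = blank_ratio,
    blank_stat = blank_stat, is_cv_limit = is_cv_limit, ppm = ppm,
    min_isotope_score = min_isotope_score, max_candidates = max_candidates,
    composite_mode = composite_mode, iqr_drop_fraction = iqr_drop_fraction,
    presence_fraction = presence_fraction, alpha = alpha,
    min_abs_log2fc = min_abs_log2fc, p_adjust = p_adjust,
    n_components = n_components, folds = folds, seed = seed
  )
  stopifnot(
    cfg$blank_ratio >= 0, cfg$blank_stat %in% c("mean", "max"),
    cfg$is_cv_limit > 0, is.na(cfg$ppm) || cfg$ppm > 0,
    cfg$min_isotope_score >= 0, cfg$min_isotope_score <= 100,
    cfg$max_candidates >= 1, cfg$max_candidates <= 3,
    cfg$composite_mode %in% c("average-counts", "average-ratios"),
    cfg$iqr_drop_fraction >= 0, cfg$iqr_drop_fraction < 1,
    cfg$presence_fraction > 0, cfg$presence_fraction <= 1,
    cfg$alpha >= 0, cfg$alpha <= 1, cfg$min_abs_log2fc >= 0,
    cfg$p_adjust %in% c("BH", "none"),
    cfg$n_components >= 1, cfg$folds >= 2, cfg$n_features >= 10
  )
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as plain key=value text
#'
#' Scalar fields are serialised one per line (`key=value`); the round trip
#' through a file reproduces the configuration exactly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    val <- if (is.null(v)) "NULL" else as.character(v)
    paste0(k, "=", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  args <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
  defaults <- pipeline_config()
  parse_val <- function(k, v) {
    if (v == "NULL") return(NULL)
    if (v == "NA") return(NA_real_)
    proto <- defaults[[k]]
    if (is.logical(proto)) as.logical(v)
    else if (is.numeric(proto) || k == "ppm") as.numeric(v)
    else v
  }
  args <- args[names(args) %in% names(defaults)]
  do.call(pipeline_config, stats::setNames(
    lapply(names(args), function(k) parse_val(k, args[[k]])), names(args)
  ))
}

# Deterministic polynomial hash of the serialised config, for provenance
# headers (not cryptographic; only change detection).
config_hash <- function(config) {
  # hash the analysis parameters, not the file-system locations
  config <- config[setdiff(names(config),
                           c("feature_table", "design", "library", "out_dir"))]
  s <- paste(vapply(names(config), function(k) {
    paste0(k, "=", paste(as.character(config[[k]]), collapse = ","))
  }, character(1)), collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_report_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order: QC (blank retention, internal-standard
#' CVs) -> known-compound annotation -> formula assignment -> composite
#' formulas and elemental ratios -> group statistics (Kruskal-Wallis +
#' pairwise-vs-reference on C/N, C/P, N/P; significant feature sets; UpSet
#' counts) -> PLS-DA with k-fold validation -> report bundle. Every stage
#' logs its input/output feature counts; identical config + seed produce a
#' byte-identical bundle. Stage failures abort with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with the in-memory results and the paths of the
#'   written report CSVs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  hdr <- paste0("ms1stoich config_hash=", config_hash(config),
                " seed=", config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$out_dir, f)
  paths <- character()

  # -- inputs -----------------------------------------------------------
  inputs <- stage("input", {
    if (config$simulate) {
      design <- synthetic_design(seed = config$seed + 1L)
      lib <- sample_formula_library(config$n_features, c(85, 500),
                                    seed = config$seed + 2L)
      groups <- unique(design$group[!design$is_blank])
      eff <- stats::setNames(lapply(seq_along(groups), function(i) {
        e <- numeric(config$n_features)
        planted <- seq_len(config$n_features) %% length(groups) == (i - 1)
        e[planted] <- 2
        e
      }), groups)
      sim <- simulate_feature_table(design, lib, effects = eff,
                                    seed = config$seed + 3L)
      say("input: simulated ", nrow(sim$table$features), " features, ",
          length(sim$table$samples), " samples (seed ", config$seed, ")")
      sim
    } else {
      if (is.null(config$feature_table) || is.null(config$design)) {
        stop("feature_table and design paths are required unless simulate=TRUE")
      }
      list(table = read_feature_table(config$feature_table),
           design = read_design(config$design), truth = NULL)
    }
  })
  table <- inputs$table
  design <- inputs$design

  # -- QC ----------------------------------------------------------------
  qc_rows <- list()
  table <- stage("qc", {
    n_in <- nrow(table$features)
    out <- table
    if (config$blank_filter) {
      out <- blank_filter(out, design, config$blank_ratio, config$blank_stat)
    }
    say("qc: blank filter ", n_in, " -> ", nrow(out$features), " features")
    qc_rows[[1]] <- data.frame(metric = "features_after_blank_filter",
                               value = nrow(out$features))
    is_ids <- intersect(attr(design, "internal_standards"),
                        out$features$feature_id)
    for (id in is_ids) {
      cv <- internal_standard_cv(out, id, design, config$is_cv_limit)
      say("qc: internal standard ", id, " CV = ",
          format(cv$cv_pct, digits = 3), "% (pass: ", cv$pass, ")")
      qc_rows[[length(qc_rows) + 1]] <-
        data.frame(metric = paste0("is_cv_pct_", id), value = cv$cv_pct)
    }
    # internal standards are known spikes: exclude from the unknown-feature set
    keep <- !out$features$feature_id %in% is_ids
    list(table = subset_features(out, which(keep)), qc_rows = qc_rows)
  })
  qc_rows <- table$qc_rows
  table <- table$table

  # -- known-compound annotation ----------------------------------------
  annotations <- NULL
  if (!is.null(config$library)) {
    annotations <- stage("annotation", {
      lib <- read_compound_library(config$library)
      ann <- match_library(table, lib)
      say("annotation: ", sum(ann$msi_level == 1L), " of ", nrow(ann),
          " features matched the compound library")
      ann
    })
    identified <- annotations$feature_id[annotations$msi_level == 1L]
    table <- subset_features(table,
                             which(!table$features$feature_id %in% identified))
  }

  # -- formula assignment ------------------------------------------------
  fcfg <- formula_config(ppm = if (is.na(config$ppm)) NULL else config$ppm,
                         min_isotope_score = config$min_isotope_score)
  assignments <- stage("assignment", {
    a <- assign_formulas(table, fcfg, k = config$max_candidates)
    say("assignment: ", length(unique(a$feature_id)), " of ",
        nrow(table$features), " features assigned >= 1 candidate formula")
    a
  })

  # -- composites and ratios --------------------------------------------
  ratios <- stage("ratios", {
    r <- feature_ratios(assignments, config$composite_mode)
    say("ratios: ", nrow(r), " composite formulas (mode ",
        config$composite_mode, "); defined C/P for ", sum(!is.na(r$cp)))
    r
  })

  # -- group statistics --------------------------------------------------
  stats_out <- stage("statistics", {
    ref <- reference_group(design)
    by_group <- ratio_values_by_group(table, ratios, design,
                                      config$presence_fraction)
    ratio_tests <- list()
    pairwise <- list()
    for (rn in c("cn", "cp", "np")) {
      v <- by_group[[rn]]
      ok <- !is.na(v)
      if (length(unique(by_group$group[ok])) < 2 || sum(ok) < 3) next
      kw <- kruskal_wallis(v[ok], by_group$group[ok])
      ratio_tests[[rn]] <- data.frame(ratio = rn, H = kw$statistic,
                                      df = kw$df, p_value = kw$p_value)
      pw <- pairwise_vs_reference(v[ok], by_group$group[ok], ref, config$alpha)
      pairwise[[rn]] <- cbind(ratio = rn, pw)
    }
    sets <- significant_feature_sets(table, design, config$alpha,
                                     config$min_abs_log2fc, config$p_adjust)
    say("statistics: significant feature sets vs ", ref, ": ",
        paste(names(sets), lengths(sets), sep = "=", collapse = ", "))
    list(
      by_group = by_group,
      ratio_tests = do.call(rbind, ratio_tests),
      pairwise = do.call(rbind, pairwise),
      sets = sets,
      upset = upset_counts(sets)
    )
  })

  # -- multivariate ------------------------------------------------------
  plsda_out <- stage("plsda", {
    nb <- design[!design$is_blank, , drop = FALSE]
    mat <- table$intensities[, nb$sample_id, drop = FALSE]
    mat <- quantile_normalize(mat)
    mat <- iqr_filter(mat, config$iqr_drop_fraction)
    mat <- log_pareto(mat)
    X <- t(mat)
    cv <- cross_validate(X, nb$group, k = config$folds,
                         n_components = config$n_components,
                         seed = config$seed + 4L)
    fit <- plsda_fit(X, nb$group, n_components = config$n_components)
    say("plsda: R2 = ", format(cv$r2, digits = 4),
        ", Q2 = ", format(cv$q2, digits = 4),
        " (", config$folds, "-fold, ", config$n_components, " components)")
    list(fit = fit, cv = cv, X = X, groups = nb$group,
         sample_id = nb$sample_id)
  })

  # -- report bundle -----------------------------------------------------
  paths <- stage("report", {
    w <- function(df, fname) {
      p <- write_report_csv(df, out_path(fname), hdr)
      paths <<- c(paths, p)
    }
    w(do.call(rbind, qc_rows), "qc_report.csv")
    if (!is.null(annotations)) w(annotations, "annotations.csv")
    w(assignments[c("feature_id", "rank", "formula", "theoretical_mass",
                    "mz_error_ppm", "rdbe", "isotope_score",
                    "nitrogen_rule_ok")], "candidates.csv")
    w(ratios, "composite_ratios.csv")
    w(stats_out$by_group, "ratio_values_by_group.csv")
    if (!is.null(stats_out$ratio_tests)) w(stats_out$ratio_tests, "ratio_tests.csv")
    if (!is.null(stats_out$pairwise)) w(stats_out$pairwise, "ratio_pairwise.csv")
    sets_df <- data.frame(
      group = rep(names(stats_out$sets), lengths(stats_out$sets)),
      feature_id = unlist(stats_out$sets, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    w(sets_df, "significant_features.csv")
    w(stats_out$upset, "upset_counts.csv")
    fit <- plsda_out$fit
    w(data.frame(statistic = c("r2", "q2", "press", "tss"),
                 value = c(plsda_out$cv$r2, plsda_out$cv$q2,
                           plsda_out$cv$press, plsda_out$cv$tss)),
      "plsda_summary.csv")
    w(data.frame(feature_id = fit$variables,
                 vip = vip_scores(fit),
                 vip_component1 = vip_scores(fit, 1)), "plsda_vip.csv")
    scores <- fit$T_scores
    colnames(scores) <- paste0("comp", seq_len(ncol(scores)))
    w(data.frame(sample_id = plsda_out$sample_id, group = plsda_out$groups,
                 scores), "plsda_scores.csv")
    writeLines(c(paste0("# ", hdr), log_lines), out_path("pipeline_log.txt"))
    c(paths, out_path("pipeline_log.txt"))
  })

  invisible(list(
    table = table, design = design, truth = inputs$truth,
    annotations = annotations, assignments = assignments, ratios = ratios,
    statistics = stats_out, plsda = plsda_out, paths = paths,
    config_hash = config_hash(config), log = log_lines
  ))
}
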