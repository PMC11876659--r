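MANIFEST_REQUIRED <- c("subject_id", "group", "age", "sex")
MANIFEST_CLINICAL <- c("vas", "bi", "joa", "fugl_meyer", "duration_months",
                       "pd2_rh", "pd2_lh", "pd2_rf", "pd2_lf")

#' Read and validate a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id, group, age, sex` plus
#' the clinical scores.  Subject ids must be unique, `group` must be
#' `"patient"` or `"control"`, `sex` must be in `{M, F, 0, 1}` and all
#' score columns must be numeric.
#'
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("manifest not found: ", path), class = "connectopath_io_error")
  }
  manifest <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(MANIFEST_REQUIRED, names(manifest))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("manifest lacks required columns: ",
                           paste(missing_cols, collapse = ", ")))
  }
  dup <- manifest$subject_id[duplicated(manifest$subject_id)]
  if (length(dup) > 0) {
    stop_validation(paste0("duplicate subject ids: ",
                           paste(unique(dup), collapse = ", ")))
  }
  bad_group <- setdiff(unique(manifest$group), c("patient", "control"))
  if (length(bad_group) > 0) {
    stop_validation(paste0("unknown group labels: ",
                           paste(bad_group, collapse = ", "),
                           " (expected 'patient' or 'control')"))
  }
  sex_to_numeric(manifest$sex)  # errors on bad vocabulary
  numeric_cols <- intersect(c("age", MANIFEST_CLINICAL), names(manifest))
  for (col in numeric_cols) {
    vals <- manifest[[col]]
    if (!is.numeric(vals)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(vals))))[1]
      stop_validation(sprintf(
        "manifest column '%s' is not numeric (first bad value '%s' at row %d)",
        col, as.character(vals[bad_row]), bad_row))
    }
  }
  manifest
}

#' Pipeline configuration
#'
#' Bundles every choice the end-to-end analysis needs: input locations,
#' frequency bands, the sparsity grid, simulation sizes for the null and
#' resampling procedures, correction methods per stage, the rule that
#' selects "altered" metrics for the clinical stages, and one master seed
#' from which all per-stage seeds are derived (so e.g. changing `n_perm`
#' does not perturb the bootstrap draws).
#'
#' @param manifest Path to the manifest CSV.
#' @param ts_dir,sc_dir Directories holding `<subject_id>_ts.tsv` /
#'   `<subject_id>_sc.tsv` files; either may be `NULL` to skip that arm.
#' @param out_dir Output directory.
#' @param tr_seconds Repetition time of the time series.
#' @param bands Subset of `c("full", "slow4", "slow5")`.
#' @param grid Sparsity grid.
#' @param metrics Metric names to compute.
#' @param n_nulls Null networks per graph for gamma/lambda/sigma (0 skips
#'   the small-world trio).
#' @param n_perm Permutations for the group comparison.
#' @param n_boot Bootstrap resamples for mediation.
#' @param correction_groups,correction_correlations Correction method per
#'   stage (`"bonferroni"` or `"bh"`).
#' @param altered_rule Which group-difference results feed the clinical
#'   stages: `"corrected"` (survive correction), `"uncorrected"`
#'   (raw p < alpha) or `"all"`.
#' @param clinical_vars Clinical columns used in correlation/mediation.
#' @param mediation_models Optional list of lists with elements `x`, `m`,
#'   `y` (variable ids; metric ids are
#'   `"<modality>_<band>_<metric>_<scope>[_<node>]"`, clinical ids are
#'   manifest column names) and optionally `covariates`.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(manifest, ts_dir = NULL, sc_dir = NULL,
                            out_dir, tr_seconds = 2,
                            bands = c("full", "slow4", "slow5"),
                            grid = sparsity_grid(),
                            metrics = c("cp", "lp", "eg", "eloc"),
                            n_nulls = 0, n_perm = 10000, n_boot = 5000,
                            correction_groups = "bonferroni",
                            correction_correlations = "bh",
                            altered_rule = c("corrected", "uncorrected", "all"),
                            clinical_vars = MANIFEST_CLINICAL,
                            mediation_models = NULL,
                            alpha = 0.05, seed = 7L) {
  altered_rule <- match.arg(altered_rule)
  known_bands <- names(fmri_bands())
  bad <- setdiff(bands, known_bands)
  if (length(bad) > 0) {
    stop_config(paste0("unknown band name(s): ", paste(bad, collapse = ", "),
                       " (known: ", paste(known_bands, collapse = ", "), ")"))
  }
  if (length(bands) == 0 && is.null(sc_dir)) {
    stop_config("nothing to analyze: no bands and no SC directory")
  }
  for (p in c(manifest, ts_dir, sc_dir)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_config(paste0("path does not exist: ", p))
    }
  }
  for (nm in c("n_perm", "n_boot")) {
    if (!is_count(get(nm))) stop_config(paste0("`", nm, "` must be a positive integer"))
  }
  structure(list(
    manifest = manifest, ts_dir = ts_dir, sc_dir = sc_dir, out_dir = out_dir,
    tr_seconds = tr_seconds, bands = bands, grid = grid, metrics = metrics,
    n_nulls = n_nulls, n_perm = n_perm, n_boot = n_boot,
    correction_groups = correction_groups,
    correction_correlations = correction_correlations,
    altered_rule = altered_rule, clinical_vars = clinical_vars,
    mediation_models = mediation_models, alpha = alpha,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file with `pipeline_config()` fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$grid) && length(raw$grid) == 3) {
    raw$grid <- do.call(sparsity_grid, as.list(raw$grid))
  }
  do.call(pipeline_config, raw)
}

metric_variable_id <- function(modality, band, metric, scope, node) {
  id <- paste(modality, band, metric, scope, sep = "_")
  ifelse(is.na(node), id, paste(id, node, sep = "_"))
}

log_stage <- function(log_path, fmt, ...) {
  msg <- sprintf(fmt, ...)
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  invisible(msg)
}

run_stage <- function(name, log_path, expr) {
  log_stage(log_path, "stage %s: start", name)
  result <- tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
          class = "connectopath_stage_error", parent = e)
  })
  log_stage(log_path, "stage %s: done", name)
  result
}

#' Run the full connectome analysis pipeline
#'
#' Executes, in order: manifest loading, functional network construction
#' per requested band (linear detrend, ideal bandpass, Pearson FC),
#' structural network ingestion, topology metrics with AUC integration,
#' covariate-adjusted permutation group comparison, partial correlation
#' of altered metrics with clinical variables (within patients), and
#' mediation analysis.  Each stage reads only prior-stage outputs, every
#' random step draws its seed from the master seed, and a rerun with the
#' same configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (also written to `report.json` and
#'   `report.txt` in `out_dir`): per-stage row counts, significant
#'   findings, software version, configuration echo and seeds.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  seed <- config$seed
  report <- list(package_version = as.character(packageVersion("connectopath")),
                 config = unclass(config)[setdiff(names(config), "grid")],
                 grid = range(config$grid),
                 seeds = list(master = seed),
                 stages = list())

  manifest <- run_stage("manifest", log_path, read_manifest(config$manifest))
  report$stages$manifest <- list(n_subjects = nrow(manifest))

  matrices <- list()
  if (!is.null(config$ts_dir) && length(config$bands) > 0) {
    bands <- fmri_bands()[config$bands]
    fc_dir <- file.path(config$out_dir, "fc")
    dir.create(fc_dir, showWarnings = FALSE)
    fc_mats <- run_stage("build-fc", log_path, {
      purrr::map(manifest$subject_id, function(id) {
        ts <- read_matrix_tsv(file.path(config$ts_dir, paste0(id, "_ts.tsv")))
        ts <- detrend_columns(ts)
        purrr::map(bands, function(bd) {
          filt <- bandpass_filter(ts, bd, config$tr_seconds)
          fc <- fc_matrix(filt, band = bd$name, subject_id = id)
          write_matrix_tsv(unclass(fc),
                           file.path(fc_dir, paste0(id, "_fc_", bd$name, ".tsv")))
          fc
        })
      }) |> purrr::list_flatten()
    })
    matrices <- c(matrices, fc_mats)
    report$stages$build_fc <- list(n_matrices = length(fc_mats))
  }
  if (!is.null(config$sc_dir)) {
    sc_mats <- run_stage("ingest-sc", log_path, {
      purrr::map(manifest$subject_id, function(id) {
        load_sc_matrix(file.path(config$sc_dir, paste0(id, "_sc.tsv")),
                       subject_id = id)
      })
    })
    matrices <- c(matrices, sc_mats)
    report$stages$ingest_sc <- list(n_matrices = length(sc_mats))
  }
  if (length(matrices) == 0) stop_config("no connectivity matrices to analyze")

  met <- run_stage("metrics", log_path, {
    names(matrices) <- paste0(
      purrr::map_chr(matrices, ~ attr(.x, "subject_id")), "_",
      purrr::map_chr(matrices, ~ attr(.x, "modality")), "_",
      purrr::map_chr(matrices, ~ attr(.x, "band")))
    metrics <- config$metrics
    if (config$n_nulls == 0) {
      metrics <- setdiff(metrics, c("gamma", "lambda", "sigma"))
    }
    out <- cohort_metrics(matrices, grid = config$grid, metrics = metrics,
                          n_null = max(config$n_nulls, 1),
                          seed = derive_seed(seed, 101))
    readr::write_csv(out$curves, file.path(config$out_dir, "metrics.csv"))
    readr::write_csv(out$auc, file.path(config$out_dir, "metrics_auc.csv"))
    out
  })
  report$stages$metrics <- list(n_curve_rows = nrow(met$curves),
                                n_auc_rows = nrow(met$auc))

  stats_tbl <- run_stage("compare", log_path, {
    out <- compare_groups(met$auc, manifest, n_perm = config$n_perm,
                          correction = config$correction_groups,
                          alpha = config$alpha,
                          seed = derive_seed(seed, 202))
    readr::write_csv(out, file.path(config$out_dir, "stats.csv"))
    out
  })
  sig <- dplyr::filter(stats_tbl, .data$significant)
  report$stages$compare <- list(
    n_tests = nrow(stats_tbl), n_significant = nrow(sig),
    significant = metric_variable_id(sig$modality, sig$band, sig$metric,
                                     sig$scope, sig$node))

  altered <- switch(config$altered_rule,
                    corrected = dplyr::filter(stats_tbl, .data$significant),
                    uncorrected = dplyr::filter(stats_tbl, .data$p < config$alpha),
                    all = stats_tbl)
  corr_tbl <- run_stage("correlate", log_path, {
    if (nrow(altered) == 0) {
      log_stage(log_path, "no altered metrics under rule '%s'; correlation stage empty",
                config$altered_rule)
      tibble::tibble()
    } else {
      out <- correlate_clinical(
        met$auc, manifest, clinical_vars = config$clinical_vars,
        metrics = dplyr::select(altered, "modality", "band", "metric",
                                "scope", "node"),
        correction = config$correction_correlations, alpha = config$alpha)
      readr::write_csv(out, file.path(config$out_dir, "correlations.csv"))
      out
    }
  })
  report$stages$correlate <- list(
    n_tests = nrow(corr_tbl),
    n_significant = if (nrow(corr_tbl)) sum(corr_tbl$significant) else 0L)

  med_tbl <- run_stage("mediate", log_path, {
    models <- config$mediation_models %||%
      suggest_mediation_models(altered, corr_tbl)
    if (length(models) == 0) {
      log_stage(log_path, "no mediation models specified or suggested; stage empty")
      tibble::tibble()
    } else {
      wide <- mediation_data(met$auc, manifest)
      fits <- purrr::map2(models, seq_along(models), function(mdl, i) {
        fit <- mediate(wide, x = mdl$x, m = mdl$m, y = mdl$y,
                       covariates = mdl$covariates %||% c("age", "sex"),
                       n_boot = config$n_boot,
                       seed = derive_seed(seed, 303 + i))
        glance(fit)
      })
      out <- dplyr::bind_rows(fits)
      readr::write_csv(out, file.path(config$out_dir, "mediation.csv"))
      out
    }
  })
  report$stages$mediate <- list(
    n_models = nrow(med_tbl),
    n_significant = if (nrow(med_tbl)) sum(med_tbl$conclusion == "significant") else 0L)

  report <- structure(report, class = "run_report")
  write_report(report, file.path(config$out_dir, "report.json"))
  log_stage(log_path, "pipeline complete")
  report
}

#' Assemble a wide per-subject table of metric AUC values and clinical data
#'
#' Metric columns are named `"<modality>_<band>_<metric>_<scope>[_<node>]"`
#' and joined to the manifest, restricted to one group (mediation and
#' clinical correlation operate within the patient group, where the
#' clinical scales vary).
#'
#' @param auc AUC tibble.
#' @param manifest Cohort manifest.
#' @param group Group to keep (default `"patient"`).
#' @return A wide tibble, one row per subject.
#' @export
mediation_data <- function(auc, manifest, group = "patient") {
  wide <- auc |>
    dplyr::mutate(variable = metric_variable_id(
      .data$modality, .data$band, .data$metric, .data$scope, .data$node)) |>
    dplyr::select("subject_id", "variable", "auc") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "auc")
  manifest |>
    dplyr::filter(.data$group == !!group) |>
    dplyr::inner_join(wide, by = "subject_id")
}

# Heuristic used when no mediation models are configured: pair an altered
# FC metric with an altered SC metric that share a significantly
# correlated clinical variable, using the shared scale as the outcome.
suggest_mediation_models <- function(altered, correlations) {
  if (nrow(altered) == 0 || is.null(correlations) || nrow(correlations) == 0) {
    return(list())
  }
  sig <- dplyr::filter(correlations, .data$significant)
  if (nrow(sig) == 0) return(list())
  sig <- dplyr::mutate(sig, variable = metric_variable_id(
    .data$modality, .data$band, .data$metric, .data$scope, .data$node))
  fc <- dplyr::filter(sig, .data$modality == "FC")
  sc <- dplyr::filter(sig, .data$modality == "SC")
  shared <- dplyr::inner_join(
    dplyr::select(fc, x = "variable", "clinical_var"),
    dplyr::select(sc, m = "variable", "clinical_var"),
    by = "clinical_var", relationship = "many-to-many")
  purrr::pmap(shared, function(x, clinical_var, m) {
    list(x = x, m = m, y = clinical_var)
  })
}

#' Write a pipeline run report
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path Path for the JSON report; a human-readable `.txt` twin is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  txt <- file.path(dirname(path), sub("\\.json$", ".txt", basename(path)))
  lines <- c(
    sprintf("connectopath %s run report", report$package_version),
    "",
    purrr::imap_chr(report$stages, function(info, nm) {
      sprintf("  %-10s %s", nm,
              paste(names(info), purrr::map_chr(info, ~ paste(.x, collapse = ",")),
                    sep = "=", collapse = "  "))
    })
  )
  writeLines(lines, txt)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> connectopath %s, %d stages\n",
              x$package_version, length(x$stages)))
  for (nm in names(x$stages)) {
    cat("  -", nm, ":",
        paste(names(x$stages[[nm]]),
              purrr::map_chr(x$stages[[nm]], ~ paste(.x, collapse = ",")),
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}
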