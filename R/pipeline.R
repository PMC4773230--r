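# End-to-end orchestration: volumes -> lung mask -> densitometric score ->
# (optional) visual-score ingest -> cohort statistics, with a
# machine-readable manifest alongside every run.

.config_version <- 1L

#' Run configuration
#'
#' All knobs of an end-to-end run. Thresholds must satisfy
#' `-1024 <= lung_low < normal_cut < ild_cut < lung_high <= -200`.
#' Unknown configuration keys are a hard error, never a warning.
#'
#' @param inputs character vector of input volumes (NIfTI files or DICOM
#'   directories); may be empty for cohort-only runs.
#' @param out_dir output directory.
#' @param segmentation a [segmentation_params].
#' @param thresholds a [cam_thresholds].
#' @param findings_csv optional visual-score findings table (see
#'   [read_warrick_findings]).
#' @param cohort_csv optional cohort table for the statistics stage.
#' @param aggregate reader aggregation mode for the visual score.
#' @param seed integer seed governing any stochastic stage.
#' @param verbose log stage progress to standard error.
#' @return A `run_config` object.
#' @export
run_config <- function(inputs = character(), out_dir = ".",
                       segmentation = segmentation_params(),
                       thresholds = cam_thresholds(),
                       findings_csv = NULL, cohort_csv = NULL,
                       aggregate = "mean", seed = 1L, verbose = TRUE) {
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(thresholds, "cam_thresholds"))
  if (thresholds$lung_low < -1024 || thresholds$lung_high > -200)
    stop("lung window must lie within [-1024, -200] HU")
  structure(list(version = .config_version, inputs = inputs,
                 out_dir = out_dir, segmentation = segmentation,
                 thresholds = thresholds, findings_csv = findings_csv,
                 cohort_csv = cohort_csv, aggregate = aggregate,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration file
#'
#' YAML key-value format with a `version` field; unknown keys are a hard
#' error.
#'
#' @param path YAML configuration file.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$version) || y$version != .config_version)
    stop("unsupported or missing config version (expected ",
         .config_version, ")")
  known <- c("version", "inputs", "out_dir", "hu_low", "hu_high",
             "normal_cut", "ild_cut", "opening_mm", "exclude_airways",
             "min_component_voxels", "findings_csv", "cohort_csv",
             "aggregate", "seed", "verbose")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  g <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  seg <- segmentation_params(
    lung_hu_low = g("hu_low", -1024), lung_hu_high = g("hu_high", -200),
    min_component_voxels = y$min_component_voxels,
    opening_radius_mm = g("opening_mm", 1),
    exclude_airways = g("exclude_airways", TRUE))
  th <- cam_thresholds(lung_low = g("hu_low", -1024),
                       normal_cut = g("normal_cut", -700),
                       ild_cut = g("ild_cut", -500),
                       lung_high = g("hu_high", -200))
  run_config(inputs = unlist(g("inputs", character())),
             out_dir = g("out_dir", "."), segmentation = seg,
             thresholds = th, findings_csv = y$findings_csv,
             cohort_csv = y$cohort_csv, aggregate = g("aggregate", "mean"),
             seed = g("seed", 1L), verbose = g("verbose", TRUE))
}

.log_stage <- function(config, stage, msg) {
  if (config$verbose)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg))
}

.load_input_volume <- function(path) {
  if (dir.exists(path)) read_dicom_series(path)
  else if (file.exists(path)) read_nifti(path)
  else stop("input not found: ", path)
}

#' Run the full pipeline
#'
#' Stages: `segment` (threshold + refinement per input volume, mask
#' written as NIfTI), `cam` (tissue histogram and fibrosis percent, JSON
#' report per volume, combined CSV), optionally `warrick` (findings CSV
#' to scores CSV) and `cohort_stats` (descriptive and subtype tables). A
#' manifest (inputs, parameters, package version, seed, completed stages)
#' is written as `manifest.json`. A failure in any stage is rethrown with
#' the stage name and input id.
#'
#' @param config a [run_config].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  cam_rows <- list()

  with_stage <- function(stage, id, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' (", id, "): ", conditionMessage(e),
           call. = FALSE))
  }

  for (path in config$inputs) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
    vol <- with_stage("segment", id, .load_input_volume(path))
    mask <- with_stage("segment", id, segment_lungs(vol, config$segmentation))
    write_mask(mask, vol, file.path(config$out_dir,
                                    paste0(id, "_lungmask.nii.gz")))
    .log_stage(config, "segment", paste0(id, ": ", sum(mask$flags),
                                         " lung voxels"))
    res <- with_stage("cam", id, cam_score(vol, mask, config$thresholds))
    h <- res$histogram
    report <- list(input = path, patient_id = vol$patient_id,
                   fibrosis_pct = res$fibrosis_pct,
                   total_lung_volume_ml = res$total_lung_volume_ml,
                   n_total_lung = h$n_total_lung,
                   n_nonfibrotic = h$n_nonfibrotic, n_ild = h$n_ild,
                   n_consolidation = h$n_consolidation)
    jsonlite::write_json(report,
                         file.path(config$out_dir, paste0(id, "_cam.json")),
                         auto_unbox = TRUE, digits = NA)
    cam_rows[[id]] <- as.data.frame(report)
    .log_stage(config, "cam", sprintf("%s: fibrosis %.1f %%", id,
                                      res$fibrosis_pct))
  }
  if (length(config$inputs) > 0) {
    stages <- c(stages, "segment", "cam")
    write.csv(do.call(rbind, cam_rows),
              file.path(config$out_dir, "cam_scores.csv"), row.names = FALSE)
  }

  if (!is.null(config$findings_csv)) {
    scores <- with_stage("warrick", config$findings_csv,
      score_warrick_table(read_warrick_findings(config$findings_csv),
                          aggregate = config$aggregate))
    write.csv(scores, file.path(config$out_dir, "warrick_scores.csv"),
              row.names = FALSE)
    stages <- c(stages, "warrick")
    .log_stage(config, "warrick", paste0(nrow(scores), " score rows"))
  }

  if (!is.null(config$cohort_csv)) {
    cohort <- with_stage("cohort_stats", config$cohort_csv,
                         read.csv(config$cohort_csv, stringsAsFactors = TRUE))
    write.csv(render_table1(cohort),
              file.path(config$out_dir, "table1_descriptives.csv"),
              row.names = FALSE)
    if ("subtype" %in% names(cohort))
      write.csv(render_table2(cohort),
                file.path(config$out_dir, "table2_by_subtype.csv"),
                row.names = FALSE)
    stages <- c(stages, "cohort_stats")
    .log_stage(config, "cohort_stats", paste0(nrow(cohort), " patients"))
  }

  manifest <- list(package = "fibroscore",
                   version = as.character(packageVersion("fibroscore")),
                   seed = config$seed, inputs = config$inputs,
                   parameters = list(
                     hu_low = config$thresholds$lung_low,
                     normal_cut = config$thresholds$normal_cut,
                     ild_cut = config$thresholds$ild_cut,
                     hu_high = config$thresholds$lung_high,
                     opening_mm = config$segmentation$opening_radius_mm,
                     exclude_airways = config$segmentation$exclude_airways,
                     aggregate = config$aggregate),
                   stages_completed = stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.table_variables <- c(
  age = "Age, years", disease_duration = "Disease duration, years",
  mrss = "mRSS", borg = "Borg score", vas_breathing = "VAS for breathing",
  haq_di = "HAQ-DI", dlco_pct = "DLco, % predicted",
  fvc_pct = "FVC, % predicted", covr_extent = "HRCT extent",
  covr_severity = "HRCT severity", covr_total = "HRCT total score",
  cam_fibrosis_pct = "Pulmonary fibrosis (%)")

.table_binaries <- c(anti_topo_I = "Anti-topoisomerase I, n (%)",
                     anti_centromere = "Anti-centromere, n (%)")

#' Baseline descriptive table
#'
#' One row per variable with mean, SD, median and IQR bounds; binary
#' variables as count (percent).
#'
#' @param cohort data frame with the standard cohort columns.
#' @return A data frame.
#' @export
render_table1 <- function(cohort) {
  rows <- list()
  for (v in intersect(names(.table_variables), names(cohort))) {
    s <- cohort_describe(cohort, v)
    rows[[v]] <- data.frame(variable = .table_variables[[v]],
                            mean = s$mean, sd = s$sd, median = s$median,
                            iqr_low = s$iqr_low, iqr_high = s$iqr_high,
                            n_pct = NA_character_)
  }
  for (v in intersect(names(.table_binaries), names(cohort))) {
    x <- cohort[[v]]
    pres <- if (is.logical(x)) x else x == levels(factor(x))[2]
    rows[[v]] <- data.frame(variable = .table_binaries[[v]],
                            mean = NA, sd = NA, median = NA,
                            iqr_low = NA, iqr_high = NA,
                            n_pct = sprintf("%d (%.1f)", sum(pres),
                                            100 * mean(pres)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive table split by disease subtype
#'
#' @param cohort data frame with a two-level `subtype` column.
#' @return A data frame with one column block per subtype (diffuse,
#'   limited).
#' @export
render_table2 <- function(cohort) {
  g <- factor(cohort$subtype)
  if (nlevels(g) != 2) stop("'subtype' must have exactly two levels")
  # diffuse block first when the conventional labels are present
  lev <- levels(g)
  if ("dcSSc" %in% lev) lev <- c("dcSSc", setdiff(lev, "dcSSc"))
  blocks <- lapply(lev, function(l) {
    t1 <- render_table1(cohort[g == l, , drop = FALSE])
    names(t1)[-1] <- paste0(l, ".", names(t1)[-1])
    t1
  })
  out <- blocks[[1]]
  for (b in blocks[-1]) out <- merge(out, b, by = "variable", sort = FALSE)
  out
}

#' Regression summary table
#'
#' @param fit a `fibro_regression` from [fit_multivariate].
#' @return A data frame with one row per covariate (coefficient, SE,
#'   partial r, t, p) and the model-level multiple R / adjusted R^2
#'   attached as attribute `"model"`.
#' @export
render_table3 <- function(fit) {
  stopifnot(inherits(fit, "fibro_regression"))
  out <- fit$coefficients
  attr(out, "model") <- fit$model
  out
}

#' Scatter plot of two cohort measures with regression line
#'
#' @param cohort data frame.
#' @param x,y column names.
#' @param xlab,ylab axis labels (default: the column names).
#' @return A ggplot object.
#' @export
plot_association <- function(cohort, x, y, xlab = x, ylab = y) {
  r <- cohort_pearson(cohort, x, y)
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = xlab, y = ylab,
                  subtitle = sprintf("Pearson r = %.3f (n = %d)", r$r, r$n)) +
    ggplot2::theme_minimal()
}
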