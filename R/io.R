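# File formats and pipeline plumbing: CSV case tables, 16-bit PNG images,
# NIfTI volumes, JSON pipeline configuration, and the end-to-end runner.

#' Read a case table from CSV
#'
#' Expects a header `case_id, <features...>, label[, synthetic]`. The
#' `synthetic` column defaults to `FALSE` when absent. Duplicate case ids,
#' non-binary labels and missing feature values are rejected with the
#' offending id or row named.
#'
#' @param path CSV file path.
#' @return Case table tibble.
#' @export
read_case_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("case_id", "label") %in% names(tab))) {
    stop_invalid("case table must have case_id and label columns",
                 class = "imagerisk_parse_error")
  }
  if (!"synthetic" %in% names(tab)) tab$synthetic <- FALSE
  tab$case_id <- as.character(tab$case_id)
  tab$synthetic <- as.logical(tab$synthetic)
  dup <- tab$case_id[duplicated(tab$case_id)]
  if (length(dup) > 0) {
    stop_invalid(paste0("duplicate case_id: ", dup[1]),
                 class = "imagerisk_parse_error")
  }
  if (!all(tab$label %in% c(0, 1))) {
    bad <- which(!tab$label %in% c(0, 1))[1]
    stop_invalid(sprintf("non-binary label in row %d", bad),
                 class = "imagerisk_parse_error")
  }
  tab$label <- as.integer(tab$label)
  feats <- feature_columns(tab)
  for (f in feats) {
    if (anyNA(tab[[f]])) {
      stop_invalid(sprintf("missing value in feature %s, row %d",
                           f, which(is.na(tab[[f]]))[1]),
                   class = "imagerisk_parse_error")
    }
  }
  tab[, c("case_id", feats, "label", "synthetic")]
}

#' Write a case table to CSV
#'
#' @param table Case table tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_case_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read / write a 2D grayscale image
#'
#' Intensities are stored on a 0..1 scale. TIFF output is 16 bit (the
#' lossless interchange format for phantoms); PNG output is 8 bit, intended
#' for quick inspection.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param path File path.
#' @return Writers return the path invisibly; readers a numeric matrix.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname write_image_tiff
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path, dpi = NULL)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Read / write a volume as NIfTI
#'
#' Voxel spacing (mm) travels in the NIfTI header.
#'
#' @param volume Numeric 3D array.
#' @param path File path (`.nii` / `.nii.gz`).
#' @param spacing Voxel spacing in mm per axis.
#' @return `write_volume_nifti` the path invisibly; `read_volume_nifti` a
#'   list with `volume` and `spacing`.
#' @export
write_volume_nifti <- function(volume, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = unclass(as.array(img)), spacing = RNifti::pixdim(img))
}

#' Pipeline configuration
#'
#' Collects every tunable of the tabular modeling pipeline with defaults at
#' the field-standard values: emphysema threshold -950 HU, fat window
#' -140..40 HU, KNN neighbourhood `k = 15`, operating threshold `T = 0.5`,
#' five score subgroups. The configuration round-trips losslessly through
#' JSON via [write_config()] / [read_config()].
#'
#' @param seed Integer seed for the whole run.
#' @param k KNN neighbourhood size.
#' @param threshold Operating threshold for the confusion matrix.
#' @param bins Number of score subgroups.
#' @param smote_multiplier Minority multiplier (`NULL` to balance to 1:1).
#' @param smote_k Minority neighbourhood size for SMOTE.
#' @param selector `"cfs"` or `"none"`.
#' @param classifier Classifier kind.
#' @param emphysema_hu Emphysema density-mask threshold (HU).
#' @param fat_hu Fat window (HU, length 2).
#' @param input,output Optional input case-table path / output directory.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, k = 15, threshold = 0.5, bins = 5,
                            smote_multiplier = NULL, smote_k = 5,
                            selector = "cfs", classifier = "knn",
                            emphysema_hu = -950, fat_hu = c(-140, 40),
                            input = NULL, output = NULL) {
  cfg <- list(seed = as.integer(seed), k = as.integer(k),
              threshold = threshold, bins = as.integer(bins),
              smote_multiplier = smote_multiplier,
              smote_k = as.integer(smote_k),
              selector = selector, classifier = classifier,
              emphysema_hu = emphysema_hu, fat_hu = fat_hu,
              input = input, output = output)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$k < 1) stop_invalid("k must be >= 1")
  if (cfg$threshold < 0 || cfg$threshold > 1) {
    stop_invalid("threshold must lie in [0, 1]")
  }
  if (cfg$bins < 2) stop_invalid("bins must be >= 2")
  if (!cfg$selector %in% c("cfs", "none")) stop_invalid("unknown selector")
  if (!cfg$classifier %in% c("knn", "random_forest", "svm", "ann")) {
    stop_invalid("unknown classifier")
  }
  if (length(cfg$fat_hu) != 2 || cfg$fat_hu[1] >= cfg$fat_hu[2]) {
    stop_invalid("fat_hu must be an increasing HU pair")
  }
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the tabular modeling pipeline end to end
#'
#' Reads (or takes) a case table, runs leave-one-case-out cross-validation
#' with SMOTE and feature selection embedded per fold, evaluates the scores,
#' and optionally writes a JSON results file plus a markdown report with the
#' subgroup odds-ratio, confusion-matrix and performance sections. The run
#' is deterministic given the configured seed.
#'
#' @param config A [pipeline_config()].
#' @param table Case table tibble; read from `config$input` when omitted.
#' @return The [evaluate_scores()] result, invisibly.
#' @export
run_pipeline <- function(config, table = NULL) {
  validate_config(config)
  if (is.null(table)) {
    if (is.null(config$input)) stop_invalid("no input table or path")
    table <- read_case_table(config$input)
  }
  n_original <- sum(!table$synthetic)
  if (config$k > n_original - 1) {
    stop_invalid(sprintf("k = %d exceeds n - 1 = %d available references",
                         config$k, n_original - 1))
  }
  smote_spec <- if (is.null(config$smote_multiplier)) {
    list(target_ratio = 1, k_neighbors = config$smote_k)
  } else {
    list(multiplier = config$smote_multiplier, k_neighbors = config$smote_k)
  }
  scores <- loco_cv(table, smote_spec = smote_spec,
                    selector = config$selector,
                    classifier = config$classifier,
                    k = config$k, seed = config$seed)
  ev <- evaluate_scores(scores, threshold = config$threshold,
                        bins = config$bins)
  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    cfg_log <- unclass(config)
    cfg_log$input <- NULL
    cfg_log$output <- NULL            # keep results path-independent
    jsonlite::write_json(
      list(config = cfg_log,
           glance = as.list(glance(ev)),
           or_table = ev$or_table,
           scores = ev$scores),
      file.path(config$output, "results.json"),
      auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
    writeLines(report_markdown(ev), file.path(config$output, "report.md"))
  }
  invisible(ev)
}

#' Markdown report of an evaluation
#'
#' Renders the odds-ratio, confusion-matrix and performance-metric sections
#' of a [evaluate_scores()] result as markdown text (ORs to 2 decimals, CI
#' bounds to 3 significant figures, percentages to 1 decimal).
#'
#' @param ev A `risk_evaluation`.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(ev) {
  or <- ev$or_table
  or_lines <- if (is.null(or)) {
    "Subgroup odds ratios undefined (single-class baseline subgroup)."
  } else {
    c("| Subgroup | Cases (pos-neg) | OR | 95% CI |",
      "|---|---|---|---|",
      vapply(seq_len(nrow(or)), function(i) {
        ci <- if (or$baseline[i]) "Baseline" else
          sprintf("[%s, %s]", signif(or$ci_low[i], 3), signif(or$ci_high[i], 3))
        sprintf("| %s | %d-%d | %.2f | %s |", or$subgroup[i],
                or$positives[i], or$negatives[i], or$odds_ratio[i], ci)
      }, character(1)))
  }
  trend_line <- if (is.null(ev$trend)) character(0) else
    sprintf("Trend across subgroups: chi2 = %.2f, p = %.3g",
            ev$trend$statistic, ev$trend$p_value)
  lines <- c(
    "# Risk model evaluation",
    "",
    sprintf("AUC = %.3f +/- %.3f (n = %d, %d positive)", ev$auc, ev$auc_se,
            nrow(ev$scores), sum(ev$scores$label)),
    "",
    "## Score-subgroup odds ratios",
    "",
    or_lines,
    "",
    trend_line,
    "",
    sprintf("## Confusion matrix (T = %.2f)", ev$threshold),
    "",
    "| | Actual + | Actual - |",
    "|---|---|---|",
    sprintf("| Predicted + | %d | %d |", ev$confusion$tp, ev$confusion$fp),
    sprintf("| Predicted - | %d | %d |", ev$confusion$fn, ev$confusion$tn),
    "",
    "## Performance",
    "",
    "| Metric | Value |",
    "|---|---|",
    sprintf("| Sensitivity | %.1f%% |", ev$metrics$sensitivity),
    sprintf("| Specificity | %.1f%% |", ev$metrics$specificity),
    sprintf("| PPV | %.1f%% |", ev$metrics$ppv),
    sprintf("| NPV | %.1f%% |", ev$metrics$npv),
    sprintf("| Accuracy | %.1f%% |", ev$metrics$accuracy)
  )
  lines
}
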