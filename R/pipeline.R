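#' Experiment configuration
#'
#' Describes one end-to-end modeling experiment: a pretreatment (preset label
#' or explicit step list), an optional wavelength selector fitted on the
#' calibration set only, a model, and the SPXY split ratio. Regression
#' targets (`"ssc"`, `"k"`) use PLS; the `"origin"` target uses PLS-DA or a
#' random forest.
#'
#' @param target `"ssc"`, `"k"` or `"origin"`.
#' @param pretreatment a [pretreatment_preset()] label (`"raw"`, `"msc"`,
#'   `"snv"`, `"1st"`, `"2nd"`, `"center"`, `"sg"`) or an explicit step list
#'   for [apply_pretreatments()].
#' @param selector `"none"`, `"cars"` or `"frog"`.
#' @param selector_config a [cars_config()] or [frog_config()]; defaults are
#'   used when omitted.
#' @param model `"pls"` for regression; `"plsda"` or `"rft"` for origin.
#' @param ratio SPXY calibration fraction.
#' @param max_lv,cv_folds model-selection settings for the final PLS(-DA).
#' @param seed master seed; the selector and model draw from seeds derived
#'   from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(target = c("ssc", "k", "origin"),
                              pretreatment = "2nd",
                              selector = c("none", "cars", "frog"),
                              selector_config = NULL,
                              model = NULL,
                              ratio = 2 / 3, max_lv = 15, cv_folds = 10,
                              seed = 1L) {
  target <- match.arg(target)
  selector <- match.arg(selector)
  model <- model %||% if (target == "origin") "plsda" else "pls"
  if (target %in% c("ssc", "k") && model != "pls") {
    abort("Regression targets require `model = \"pls\"`.")
  }
  if (target == "origin" && !model %in% c("plsda", "rft")) {
    abort("The origin target requires `model` = \"plsda\" or \"rft\".")
  }
  structure(list(target = target, pretreatment = pretreatment,
                 selector = selector, selector_config = selector_config,
                 model = model, ratio = ratio, max_lv = max_lv,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "experiment_config")
}

method_label <- function(cfg) {
  pre <- if (is.character(cfg$pretreatment)) toupper(cfg$pretreatment)
         else "custom"
  parts <- c(pre,
             if (cfg$selector != "none") toupper(cfg$selector),
             switch(cfg$model, pls = "PLS", plsda = "PLS-DA", rft = "RFT"))
  paste(parts, collapse = "-")
}

prepare_dataset <- function(data, cfg) {
  if (inherits(data, "synthetic_config")) {
    data <- generate_spectra_dataset(data)$dataset
  }
  stopifnot(is_spectra_dataset(data))
  steps <- if (is.character(cfg$pretreatment) &&
               length(cfg$pretreatment) == 1) {
    pretreatment_preset(cfg$pretreatment)
  } else {
    cfg$pretreatment
  }
  apply_pretreatments(data, steps)
}

run_selector <- function(cfg, X_cal, y_cal, task) {
  sel_seed <- cfg$seed + 1000L
  if (cfg$selector == "cars") {
    sc <- cfg$selector_config %||% cars_config(seed = sel_seed)
    list(trace = cars_select(X_cal, y_cal, sc, task = task))
  } else if (cfg$selector == "frog") {
    sc <- cfg$selector_config %||% frog_config(seed = sel_seed)
    list(trace = frog_select(X_cal, y_cal, sc, task = task))
  } else {
    list(trace = NULL)
  }
}

#' Run a quantitative (regression) experiment
#'
#' Executes the full chain on a spectra dataset (or a
#' [synthetic_config()], which is generated first): pretreatment, SPXY
#' split, optional wavelength selection on the calibration rows only, PLS
#' with cross-validated latent-variable count, and evaluation of both sets.
#'
#' @param data a `spectra_ds` (reflectance) or a `synthetic_config`.
#' @param cfg an [experiment_config()] with a regression target.
#' @return An `experiment_report`: metrics tibble (`tidy()` it or read
#'   `$metrics`), the fitted model, the selection trace, the split and the
#'   provenance log.
#' @export
#' @examples
#' \donttest{
#' cfg <- experiment_config("ssc", pretreatment = "raw", selector = "none")
#' rep <- run_quantitative(synthetic_config(n_samples = 40, n_bands = 40), cfg)
#' rep$metrics
#' }
run_quantitative <- function(data, cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!cfg$target %in% c("ssc", "k")) {
    abort("`run_quantitative()` needs a regression target (ssc or k).")
  }
  ds <- prepare_dataset(data, cfg)
  y_all <- ds[[cfg$target]]
  if (all(is.na(y_all))) {
    abort(sprintf("Dataset has no `%s` values.", cfg$target))
  }
  split <- spxy_split(spectra_matrix(ds), y_all, ratio = cfg$ratio)
  cal <- subset_samples(ds, split$calibration)
  pred <- subset_samples(ds, split$prediction)

  sel <- run_selector(cfg, spectra_matrix(cal), cal[[cfg$target]],
                      task = "regression")
  if (!is.null(sel$trace)) {
    cal <- restrict_dataset(cal, sel$trace$selected_indices, cfg$selector)
    pred <- restrict_dataset(pred, sel$trace$selected_indices, cfg$selector)
  }
  model <- fit_pls(spectra_matrix(cal), cal[[cfg$target]],
                   max_lv = cfg$max_lv, cv_folds = cfg$cv_folds)
  metrics <- dplyr::bind_rows(
    evaluate_regression(cal[[cfg$target]],
                        predict_pls(model, cal), "calibration"),
    evaluate_regression(pred[[cfg$target]],
                        predict_pls(model, pred), "prediction")
  )
  metrics <- dplyr::mutate(metrics, component = cfg$target,
                           method = method_label(cfg), .before = 1)
  structure(list(metrics = metrics, model = model, selection = sel$trace,
                 split = split, config = cfg, provenance = provenance(cal)),
            class = "experiment_report")
}

#' Run an origin-discrimination experiment
#'
#' As [run_quantitative()], but the SPXY response distance uses the
#' integer-coded class, and the model is PLS-DA or a random forest; metrics
#' are per-set percent accuracies.
#'
#' @inheritParams run_quantitative
#' @param cfg an [experiment_config()] with `target = "origin"`.
#' @return An `experiment_report`.
#' @export
run_discrimination <- function(data, cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$target != "origin") {
    abort("`run_discrimination()` needs `target = \"origin\"`.")
  }
  ds <- prepare_dataset(data, cfg)
  labels <- ds$origin_class
  if (all(is.na(labels))) abort("Dataset has no `origin_class` labels.")
  y_code <- as.numeric(factor(labels))
  split <- spxy_split(spectra_matrix(ds), y_code, ratio = cfg$ratio)
  cal <- subset_samples(ds, split$calibration)
  pred <- subset_samples(ds, split$prediction)
  if (length(unique(cal$origin_class)) < 2) {
    abort(paste("Single-class calibration set after the split;",
                "check class balance / stratification."))
  }

  sel <- run_selector(cfg, spectra_matrix(cal), cal$origin_class,
                      task = "classification")
  if (!is.null(sel$trace)) {
    cal <- restrict_dataset(cal, sel$trace$selected_indices, cfg$selector)
    pred <- restrict_dataset(pred, sel$trace$selected_indices, cfg$selector)
  }
  if (cfg$model == "plsda") {
    model <- fit_plsda(spectra_matrix(cal), cal$origin_class,
                       max_lv = cfg$max_lv, cv_folds = cfg$cv_folds)
    cal_hat <- predict_plsda(model, cal)
    pred_hat <- predict_plsda(model, pred)
  } else {
    model <- fit_rft(spectra_matrix(cal), cal$origin_class,
                     seed = cfg$seed + 2000L)
    cal_hat <- predict_rft(model, cal)
    pred_hat <- predict_rft(model, pred)
  }
  metrics <- dplyr::bind_rows(
    evaluate_classification(cal$origin_class, cal_hat, "calibration"),
    evaluate_classification(pred$origin_class, pred_hat, "prediction")
  )
  metrics <- dplyr::mutate(metrics, component = "origin",
                           method = method_label(cfg), .before = 1)
  structure(list(metrics = metrics, model = model, selection = sel$trace,
                 split = split, config = cfg, provenance = provenance(cal)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("# Experiment: %s\n", method_label(x$config)))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) x$metrics

#' @export
glance.experiment_report <- function(x, ...) {
  tidyr::pivot_wider(
    x$metrics, id_cols = c("component", "method"),
    names_from = "set",
    values_from = dplyr::any_of(c("r2", "rmse", "accuracy")),
    names_glue = "{.value}_{set}")
}

#' Summarize experiments as a comparison table
#'
#' Aligns one row per experiment over pretreatment x selector x model, with
#' the calibration/prediction R^2 and RMSE columns for regression reports and
#' accuracy columns for classification reports. Mixed inputs are returned as
#' two tables in a named list.
#'
#' @param ... `experiment_report` objects, or a single list of them.
#' @return A tibble, or a named list of two tibbles (`regression`,
#'   `classification`) when both kinds are supplied.
#' @export
make_report <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && is.list(reports[[1]]) &&
      !inherits(reports[[1]], "experiment_report")) {
    reports <- reports[[1]]
  }
  if (!length(reports)) abort("Need at least one report.")
  rows <- purrr::map(reports, glance)
  is_reg <- purrr::map_lgl(rows, ~"r2_calibration" %in% names(.x))
  reg <- dplyr::bind_rows(rows[is_reg])
  cls <- dplyr::bind_rows(rows[!is_reg])
  if (nrow(reg) && nrow(cls)) {
    list(regression = rename_metric_cols(reg),
         classification = rename_metric_cols(cls))
  } else if (nrow(reg)) {
    rename_metric_cols(reg)
  } else {
    rename_metric_cols(cls)
  }
}

rename_metric_cols <- function(df) {
  lookup <- c(r2_cal = "r2_calibration", rmsec = "rmse_calibration",
              r2_pred = "r2_prediction", rmsep = "rmse_prediction",
              accuracy_cal = "accuracy_calibration",
              accuracy_pred = "accuracy_prediction")
  dplyr::rename(df, dplyr::any_of(lookup))
}
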