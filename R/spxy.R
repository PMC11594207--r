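#' SPXY calibration/prediction partitioning
#'
#' Sample set partitioning based on joint x-y distances: Euclidean distances
#' are computed separately in predictor space and response space, each is
#' normalized by its maximum, and their sum `d_xy = d_x/max(d_x) +
#' d_y/max(d_y)` drives Kennard-Stone selection — the pair at maximal joint
#' distance seeds the calibration set, then the sample maximizing the minimum
#' distance to the already-selected set is added until the requested
#' calibration size is reached. Deterministic; ties go to the lowest sample
#' index.
#'
#' @param X numeric matrix (n x p) or `spectra_ds`.
#' @param y numeric response of length n (for a `spectra_ds`, the column name
#'   `"ssc"`/`"k"`, or `"origin_class"` to use integer-coded classes).
#' @param ratio calibration fraction (default 2/3, the conventional 2:1
#'   calibration:prediction split); the calibration count is
#'   `round(n * ratio)`.
#' @return A list of class `spxy_split` with `calibration` (indices in
#'   selection order), `prediction` and `ratio`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' spxy_split(X, rnorm(10), ratio = 2 / 3)
spxy_split <- function(X, y, ratio = 2 / 3) {
  if (is_spectra_dataset(X)) {
    stopifnot(is.character(y))
    ds <- X
    y <- if (y == "origin_class") as.numeric(factor(ds$origin_class))
         else ds[[y]]
    X <- spectra_matrix(ds)
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) abort("SPXY needs at least 3 samples.")
  if (length(y) != n) abort("`y` length must equal nrow(X).")
  if (!all(is.finite(y)) || sd(y) < 1e-12) {
    abort("SPXY needs a finite response with nonzero spread.")
  }
  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(y))
  if (max(dx) <= 0) abort("SPXY undefined: all samples identical in X.")
  d <- dx / max(dx) + dy / max(dy)

  n_cal <- round(n * ratio)
  n_cal <- max(2L, min(n - 1L, as.integer(n_cal)))

  # seed: pair at maximal joint distance (lowest indices on ties)
  flat <- which(d == max(d), arr.ind = TRUE)
  flat <- flat[order(flat[, 1], flat[, 2]), , drop = FALSE]
  sel <- sort(unname(flat[1, ]))
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    mind <- vapply(rest, function(i) min(d[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])           # ties -> lowest index
  }
  structure(list(calibration = sel,
                 prediction = setdiff(seq_len(n), sel),
                 ratio = ratio),
            class = "spxy_split")
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("# SPXY split: %d calibration / %d prediction (ratio %.3f)\n",
              length(x$calibration), length(x$prediction), x$ratio))
  invisible(x)
}

#' Regression and classification evaluation metrics
#'
#' `evaluate_regression()` reports the coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot` (not a squared correlation) and the root mean
#' square error; `evaluate_classification()` reports percent accuracy.
#'
#' @param y_true,y_hat numeric vectors of equal length (n >= 2).
#' @param set_tag label for the evaluated set (`"calibration"`,
#'   `"prediction"`, ...).
#' @return A one-row tibble: `set`, `n`, then `r2` and `rmse`, or `accuracy`.
#' @export
evaluate_regression <- function(y_true, y_hat, set_tag = "calibration") {
  if (length(y_true) != length(y_hat)) abort("Length mismatch.")
  if (length(y_true) < 2) abort("Need n >= 2 to evaluate.")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst < 1e-24) abort("Zero-variance y_true: R^2 undefined.")
  ssr <- sum((y_true - y_hat)^2)
  tibble(set = set_tag, n = length(y_true),
         r2 = 1 - ssr / sst,
         rmse = sqrt(mean((y_true - y_hat)^2)))
}

#' @rdname evaluate_regression
#' @param labels_true,labels_hat class label vectors of equal length.
#' @export
evaluate_classification <- function(labels_true, labels_hat,
                                    set_tag = "calibration") {
  if (length(labels_true) != length(labels_hat)) abort("Length mismatch.")
  if (length(labels_true) < 2) abort("Need n >= 2 to evaluate.")
  tibble(set = set_tag, n = length(labels_true),
         accuracy = 100 * mean(as.character(labels_true) ==
                                 as.character(labels_hat)))
}
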