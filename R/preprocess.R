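#' Reflectance to absorbance conversion
#'
#' Chemometric models are usually built on apparent absorbance
#' `A = log10(1/R)`, which linearizes concentration effects under a
#' Beer-Lambert view of diffuse reflectance. Reflectance values are floored at
#' `floor` before taking the log so that sensor noise dipping to zero cannot
#' produce infinities.
#'
#' @param ds a reflectance-space `spectra_ds`.
#' @param floor reflectance floor guarding the logarithm.
#' @return The dataset in absorbance space.
#' @export
#' @examples
#' sim <- generate_spectra_dataset(synthetic_config(n_samples = 5))
#' to_absorbance(sim$dataset)
to_absorbance <- function(ds, floor = 1e-6) {
  stopifnot(is_spectra_dataset(ds))
  if (spectra_space(ds) != "reflectance") {
    abort("`to_absorbance()` expects a reflectance-space dataset.")
  }
  R <- spectra_matrix(ds)
  R <- pmax(R, floor)
  if (any(R <= 0)) {
    bad <- unique(ds$sample_id[which(rowSums(R <= 0) > 0)])
    abort(sprintf("Nonpositive reflectance after flooring in sample(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  set_spectra_matrix(ds, log10(1 / R), space = "absorbance",
                     step = "to_absorbance")
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum (row) to mean 0 and standard deviation 1,
#' removing per-sample multiplicative scatter and additive offsets. The
#' sample (n-1 denominator) standard deviation is used, following common
#' chemometric practice; set `population_sd = TRUE` for the n denominator.
#'
#' @param ds a `spectra_ds` with at least two bands.
#' @param population_sd use the population (n denominator) sd.
#' @return The transformed dataset.
#' @export
snv <- function(ds, population_sd = FALSE) {
  stopifnot(is_spectra_dataset(ds))
  X <- spectra_matrix(ds)
  if (ncol(X) < 2) abort("SNV needs at least 2 bands.")
  mu <- rowMeans(X)
  ss <- sqrt(rowSums((X - mu)^2) /
               (ncol(X) - if (population_sd) 0 else 1))
  if (any(ss < 1e-12)) {
    abort(sprintf("SNV undefined for constant spectrum in sample(s): %s.",
                  paste(ds$sample_id[ss < 1e-12], collapse = ", ")))
  }
  set_spectra_matrix(ds, (X - mu) / ss, step = "snv")
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum (ordinary least squares,
#' `x ~ a + b * ref`) and inverts the fitted affine distortion:
#' `corrected = (x - a) / b`. With the default reference — the mean spectrum
#' of the dataset — this removes the additive/multiplicative scatter pattern
#' that path-length variation imprints on diffuse-reflectance measurements.
#'
#' @param ds a `spectra_ds` (n >= 2 when `reference` is omitted).
#' @param reference optional reference spectrum (length p); defaults to the
#'   column-mean spectrum.
#' @return The corrected dataset; the reference used is stored in the
#'   `msc_reference` attribute for application to new data.
#' @export
msc <- function(ds, reference = NULL) {
  stopifnot(is_spectra_dataset(ds))
  X <- spectra_matrix(ds)
  if (is.null(reference)) {
    if (nrow(X) < 2) abort("MSC needs n >= 2 to form a mean reference.")
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X)) {
    abort("MSC reference length must equal the number of bands.")
  }
  ref_c <- reference - mean(reference)
  denom <- sum(ref_c^2)
  if (denom < 1e-24) abort("MSC reference is constant.")
  out <- X
  for (i in seq_len(nrow(X))) {
    b <- sum((X[i, ] - mean(X[i, ])) * ref_c) / denom
    if (abs(b) < 1e-12) {
      abort(sprintf("MSC slope ~ 0 for sample %s.", ds$sample_id[i]))
    }
    a <- mean(X[i, ]) - b * mean(reference)
    out[i, ] <- (X[i, ] - a) / b
  }
  res <- set_spectra_matrix(ds, out, step = "msc")
  attr(res, "msc_reference") <- reference
  res
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a Savitzky-Golay convolution filter row-wise: a local polynomial
#' of order `polyorder` is fitted over a sliding window of `window` points and
#' evaluated (or differentiated `deriv` times) at the centre. `deriv = 0` is
#' smoothing; `deriv = 1`/`2` are the first/second derivative pretreatments.
#' Derivatives are per band-index step, not per nm. Edges are handled by the
#' filter's polynomial edge rows, so the band count is preserved.
#'
#' @param ds a `spectra_ds` with `p >= window`.
#' @param window odd window length (> `polyorder`).
#' @param polyorder polynomial order.
#' @param deriv derivative order, 0, 1 or 2 (<= `polyorder`).
#' @return The filtered dataset.
#' @export
sg_filter <- function(ds, window = 15, polyorder = 3, deriv = 0) {
  stopifnot(is_spectra_dataset(ds))
  cfg_err <- function(msg) abort(msg, class = "hsichemo_config_error")
  if (window %% 2 != 1) cfg_err("`window` must be odd.")
  if (window <= polyorder) cfg_err("`window` must exceed `polyorder`.")
  if (!deriv %in% 0:2) cfg_err("`deriv` must be 0, 1 or 2.")
  if (deriv > polyorder) cfg_err("`deriv` must not exceed `polyorder`.")
  X <- spectra_matrix(ds)
  if (ncol(X) < window) cfg_err("Need at least `window` bands.")
  filt <- signal::sgolay(p = polyorder, n = window, m = deriv)
  out <- t(apply(X, 1, function(row) signal::sgolayfilt(row, filt)))
  set_spectra_matrix(
    ds, out,
    step = sprintf("sg_filter(window=%d,polyorder=%d,deriv=%d)",
                   window, polyorder, deriv))
}

#' Mean centering
#'
#' Subtracts the per-band (column) mean. The means are stored in the
#' `center_means` attribute so that new data can be centred consistently with
#' [apply_centering()].
#'
#' @param ds a `spectra_ds` with n >= 2.
#' @return The centred dataset.
#' @export
mean_center <- function(ds) {
  stopifnot(is_spectra_dataset(ds))
  X <- spectra_matrix(ds)
  if (nrow(X) < 2) abort("Mean centering needs n >= 2.")
  mu <- colMeans(X)
  res <- set_spectra_matrix(ds, sweep(X, 2, mu, "-"), step = "mean_center")
  attr(res, "center_means") <- mu
  res
}

#' @rdname mean_center
#' @param means stored column means (e.g. `attr(centred, "center_means")`).
#' @export
apply_centering <- function(ds, means) {
  stopifnot(is_spectra_dataset(ds))
  X <- spectra_matrix(ds)
  if (length(means) != ncol(X)) abort("`means` length must equal band count.")
  set_spectra_matrix(ds, sweep(X, 2, means, "-"), step = "mean_center(applied)")
}

#' Declarative pretreatment pipelines
#'
#' Applies an ordered list of pretreatment steps to a dataset. Each step is
#' either a function name (`"to_absorbance"`, `"snv"`, `"msc"`,
#' `"mean_center"`, `"sg_filter"`) or a named list
#' `list(fn = "sg_filter", window = 15, polyorder = 3, deriv = 2)`.
#' `pretreatment_preset()` returns the step lists for the standard method
#' labels used in banana-quality work: `"raw"`, `"msc"`, `"snv"`, `"1st"`,
#' `"2nd"`, `"center"`, `"sg"` (all on absorbance).
#'
#' @param ds a `spectra_ds`.
#' @param steps list of steps as described above.
#' @return The pretreated dataset, provenance extended per step.
#' @export
apply_pretreatments <- function(ds, steps) {
  fns <- list(to_absorbance = to_absorbance, snv = snv, msc = msc,
              sg_filter = sg_filter, mean_center = mean_center)
  for (step in steps) {
    if (is.character(step)) {
      fn_name <- step; args <- list()
    } else {
      fn_name <- step$fn %||% step[["fn"]]
      args <- step[setdiff(names(step), "fn")]
    }
    fn <- fns[[fn_name]]
    if (is.null(fn)) abort(sprintf("Unknown pretreatment `%s`.", fn_name))
    ds <- do.call(fn, c(list(ds), args))
  }
  ds
}

#' @rdname apply_pretreatments
#' @param method one of `"raw"`, `"msc"`, `"snv"`, `"1st"`, `"2nd"`,
#'   `"center"`, `"sg"`.
#' @param window,polyorder Savitzky-Golay parameters used by the derivative
#'   and smoothing presets.
#' @export
pretreatment_preset <- function(method = c("raw", "msc", "snv", "1st", "2nd",
                                           "center", "sg"),
                                window = 15, polyorder = 3) {
  method <- match.arg(method)
  sg_step <- function(d) list(fn = "sg_filter", window = window,
                              polyorder = polyorder, deriv = d)
  switch(method,
    raw = list("to_absorbance"),
    msc = list("to_absorbance", "msc"),
    snv = list("to_absorbance", "snv"),
    `1st` = list("to_absorbance", sg_step(1)),
    `2nd` = list("to_absorbance", sg_step(2)),
    center = list("to_absorbance", "mean_center"),
    sg = list("to_absorbance", sg_step(0))
  )
}
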