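#' Spectra datasets
#'
#' A spectra dataset is a wide tibble holding one row per sample: the metadata
#' columns `sample_id`, `ssc` (soluble solids content, %), `k` (potassium,
#' mg/100 g) and `origin_class`, followed by one numeric column per wavelength,
#' named by the wavelength in nm with two-decimal precision (e.g. `"840.30"`).
#' Two attributes travel with the object: `space`, flagging whether the
#' spectral values are `"reflectance"` or `"absorbance"`, and `provenance`, an
#' append-only character log of the transforms applied so far.
#'
#' @param X numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, one per column of `X`.
#' @param sample_id character vector of sample identifiers (default
#'   `"s1"`, `"s2"`, ...).
#' @param ssc,k optional numeric response vectors (length `nrow(X)`).
#' @param origin_class optional character/factor class labels.
#' @param space `"reflectance"` or `"absorbance"`.
#' @param provenance character vector of transform descriptions.
#'
#' @return A tibble of class `spectra_ds`.
#' @export
#' @examples
#' ds <- spectra_dataset(matrix(runif(20), 4, 5), wavelengths = seq(400, 800, 100))
#' spectra_matrix(ds)
spectra_dataset <- function(X, wavelengths, sample_id = NULL,
                            ssc = NULL, k = NULL, origin_class = NULL,
                            space = c("reflectance", "absorbance"),
                            provenance = character()) {
  X <- as.matrix(X)
  space <- match.arg(space)
  n <- nrow(X)
  p <- ncol(X)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != p) {
    abort(sprintf("`wavelengths` has length %d but `X` has %d columns.",
                  length(wavelengths), p))
  }
  if (p >= 2 && any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing.")
  }
  if (any(!is.finite(X))) abort("`X` contains non-finite values.")
  sample_id <- sample_id %||% paste0("s", seq_len(n))
  check_len <- function(v, nm) {
    if (!is.null(v) && length(v) != n) {
      abort(sprintf("`%s` must have length %d (one per sample).", nm, n))
    }
  }
  check_len(sample_id, "sample_id"); check_len(ssc, "ssc")
  check_len(k, "k"); check_len(origin_class, "origin_class")

  out <- tibble(
    sample_id = as.character(sample_id),
    ssc = if (is.null(ssc)) NA_real_ else as.numeric(ssc),
    k = if (is.null(k)) NA_real_ else as.numeric(k),
    origin_class = if (is.null(origin_class)) NA_character_ else
      as.character(origin_class)
  )
  spec <- as_tibble(X, .name_repair = "minimal")
  names(spec) <- format_wavelength(wavelengths)
  out <- dplyr::bind_cols(out, spec)
  attr(out, "space") <- space
  attr(out, "provenance") <- as.character(provenance)
  attr(out, "wavelengths") <- wavelengths   # full precision; names are 2 dp
  class(out) <- c("spectra_ds", class(out))
  out
}

format_wavelength <- function(wl) sprintf("%.2f", wl)

meta_cols <- c("sample_id", "ssc", "k", "origin_class")

#' @rdname spectra_dataset
#' @param ds a `spectra_ds` object.
#' @export
is_spectra_dataset <- function(ds) inherits(ds, "spectra_ds")

#' @rdname spectra_dataset
#' @export
spectra_matrix <- function(ds) {
  stopifnot(is_spectra_dataset(ds))
  X <- as.matrix(ds[, setdiff(names(ds), meta_cols), drop = FALSE])
  rownames(X) <- ds$sample_id
  X
}

#' @rdname spectra_dataset
#' @export
wavelengths <- function(ds) {
  stopifnot(is_spectra_dataset(ds))
  attr(ds, "wavelengths", exact = TRUE) %||%
    as.numeric(setdiff(names(ds), meta_cols))
}

#' @rdname spectra_dataset
#' @export
spectra_space <- function(ds) attr(ds, "space", exact = TRUE)

#' @rdname spectra_dataset
#' @export
provenance <- function(ds) attr(ds, "provenance", exact = TRUE) %||% character()

#' Replace the spectral block of a dataset
#'
#' Internal workhorse used by every pretreatment: swaps in a transformed
#' spectral matrix (same shape) and appends a provenance entry.
#'
#' @param ds a `spectra_ds`.
#' @param X replacement matrix, `n x p` matching `ds`.
#' @param space new value space, defaulting to the current one.
#' @param step provenance entry to append (character scalar), or `NULL`.
#' @return The updated `spectra_ds`.
#' @keywords internal
set_spectra_matrix <- function(ds, X, space = spectra_space(ds), step = NULL) {
  old <- spectra_matrix(ds)
  if (!all(dim(X) == dim(old))) {
    abort("Replacement spectral matrix must preserve the dataset shape.")
  }
  if (any(!is.finite(X))) {
    abort(sprintf("Transform `%s` produced non-finite spectral values.",
                  step %||% "<unnamed>"))
  }
  spectra_dataset(
    X, wavelengths(ds), sample_id = ds$sample_id,
    ssc = if (all(is.na(ds$ssc))) NULL else ds$ssc,
    k = if (all(is.na(ds$k))) NULL else ds$k,
    origin_class = if (all(is.na(ds$origin_class))) NULL else ds$origin_class,
    space = space,
    provenance = c(provenance(ds), step)
  )
}

subset_samples <- function(ds, idx) {
  X <- spectra_matrix(ds)[idx, , drop = FALSE]
  spectra_dataset(
    X, wavelengths(ds), sample_id = ds$sample_id[idx],
    ssc = if (all(is.na(ds$ssc))) NULL else ds$ssc[idx],
    k = if (all(is.na(ds$k))) NULL else ds$k[idx],
    origin_class = if (all(is.na(ds$origin_class))) NULL else
      ds$origin_class[idx],
    space = spectra_space(ds), provenance = provenance(ds)
  )
}

#' Read and write spectra CSV files
#'
#' The on-disk dialect is the wide layout of [spectra_dataset()]: columns
#' `sample_id`, `ssc`, `k`, `origin_class`, then reflectance (or absorbance)
#' values in columns named by wavelength (nm, two decimals).
#'
#' @param ds a `spectra_ds`.
#' @param path file path.
#' @param space value space to assume when reading (`"reflectance"` by
#'   default; the CSV itself does not record it).
#' @return `read_spectra_csv()` returns a `spectra_ds`;
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(is_spectra_dataset(ds))
  readr::write_csv(as_tibble(as.data.frame(ds)), path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, space = c("reflectance", "absorbance")) {
  space <- match.arg(space)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(meta_cols, names(df))
  if (length(missing)) {
    abort(sprintf("Spectra CSV lacks required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  wl_cols <- setdiff(names(df), meta_cols)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(is.na(wl))) {
    abort("Spectra CSV has non-numeric wavelength column names.")
  }
  spectra_dataset(
    as.matrix(df[, wl_cols, drop = FALSE]), wl,
    sample_id = df$sample_id,
    ssc = if (all(is.na(df$ssc))) NULL else df$ssc,
    k = if (all(is.na(df$k))) NULL else df$k,
    origin_class = if (all(is.na(df$origin_class))) NULL else df$origin_class,
    space = space
  )
}

#' @export
print.spectra_ds <- function(x, ...) {
  cat(sprintf("# Spectra dataset: %d samples x %d bands (%s), %.2f-%.2f nm\n",
              nrow(x), length(wavelengths(x)), spectra_space(x),
              min(wavelengths(x)), max(wavelengths(x))))
  if (length(provenance(x))) {
    cat("# Provenance:", paste(provenance(x), collapse = " -> "), "\n")
  }
  NextMethod()
  invisible(x)
}

#' Plot spectra as curves over wavelength
#'
#' @param object a `spectra_ds`.
#' @param colour_by metadata column used for the colour aesthetic
#'   (`"origin_class"`, `"ssc"`, `"k"` or `NULL`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_ds <- function(object, colour_by = "origin_class", ...) {
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(object)),
    cols = -dplyr::all_of(meta_cols),
    names_to = "wavelength", values_to = "value"
  )
  long$wavelength <- as.numeric(long$wavelength)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength, y = .data$value, group = .data$sample_id
  ))
  if (!is.null(colour_by) && colour_by %in% meta_cols &&
      !all(is.na(object[[colour_by]]))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour_by]]),
                                alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.6)
  }
  p + ggplot2::labs(x = "Wavelength (nm)",
                    y = spectra_space(object)) +
    ggplot2::theme_minimal()
}
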