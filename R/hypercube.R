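#' Hyperspectral cubes
#'
#' A `hypercube` wraps a `rows x cols x bands` numeric array together with its
#' wavelength axis (nm, strictly increasing) and a `kind` flag distinguishing
#' raw detector counts from calibrated reflectance. Reflectance cubes are
#' expected to stay within `[-0.5, 2]` — a generous band around the physical
#' `[0, 1]` that tolerates detector noise.
#'
#' @param data numeric 3-d array, `rows x cols x bands`.
#' @param wavelengths numeric vector (nm), length `dim(data)[3]`.
#' @param kind `"raw"` or `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3) abort("`data` must be a 3-d array.")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3]) {
    abort(sprintf("Cube has %d bands but %d wavelengths were given.",
                  dim(data)[3], length(wavelengths)))
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be finite and strictly increasing.")
  }
  if (kind == "reflectance" &&
      (min(data) < -0.5 || max(data) > 2)) {
    abort("Reflectance cube values outside the tolerated [-0.5, 2] range.")
  }
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("# Hypercube: %d x %d pixels, %d bands (%s), %.2f-%.2f nm\n",
              d[1], d[2], d[3], x$kind,
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# ENVI data-type codes supported for I/O
envi_dtypes <- list(
  `2` = list(what = "integer", size = 2),
  `3` = list(what = "integer", size = 4),
  `4` = list(what = "double",  size = 4),
  `5` = list(what = "double",  size = 8),
  `12` = list(what = "integer", size = 2, unsigned = TRUE)
)

envi_format_error <- function(msg) {
  abort(msg, class = "hsichemo_format_error")
}

#' Read and write ENVI-format hyperspectral cubes
#'
#' The ENVI format stores a cube as a flat binary file plus a text `.hdr`
#' describing its shape, data type, byte order, interleave (`bsq`, `bil` or
#' `bip`) and wavelength list. `read_envi()` takes the header path (the binary
#' is the same path without the `.hdr` extension, or as named by the header's
#' sibling); `write_envi()` produces the pair.
#'
#' @param header_path path to the `.hdr` file.
#' @param cube a `hypercube`.
#' @param path output path for the binary file; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data-type code (2 = int16, 3 = int32, 4 = float32,
#'   5 = float64, 12 = uint16). The default, 5, round-trips doubles exactly.
#' @return `read_envi()` returns a `hypercube` (kind `"raw"` unless the header
#'   carries `reflectance = 1`); `write_envi()` returns `path` invisibly.
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) {
    envi_format_error(sprintf("ENVI header not found: %s", header_path))
  }
  hdr <- parse_envi_header(header_path)
  for (fld in c("samples", "lines", "bands", "data type", "interleave")) {
    if (is.null(hdr[[fld]])) {
      envi_format_error(sprintf("ENVI header lacks required field `%s`.", fld))
    }
  }
  if (is.null(hdr$wavelength)) {
    envi_format_error("ENVI header lacks wavelength metadata.")
  }
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bsq", "bil", "bip")) {
    envi_format_error(sprintf("Unsupported ENVI interleave `%s`.", interleave))
  }
  dt <- envi_dtypes[[as.character(hdr$`data type`)]]
  if (is.null(dt)) {
    envi_format_error(sprintf("Unsupported ENVI data type %s.",
                              hdr$`data type`))
  }
  rows <- as.integer(hdr$lines); cols <- as.integer(hdr$samples)
  bands <- as.integer(hdr$bands)
  wl <- hdr$wavelength
  if (length(wl) != bands) {
    envi_format_error(sprintf(
      "Header declares %d bands but lists %d wavelengths.", bands, length(wl)))
  }
  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) {
    envi_format_error(sprintf("ENVI binary not found: %s", bin_path))
  }
  n <- rows * cols * bands
  expected_bytes <- n * dt$size
  actual_bytes <- file.info(bin_path)$size
  if (actual_bytes != expected_bytes) {
    envi_format_error(sprintf(
      "ENVI binary is %d bytes but header implies %d (%d x %d x %d, %d-byte).",
      actual_bytes, expected_bytes, rows, cols, bands, dt$size))
  }
  endian <- if (identical(as.integer(hdr$`byte order` %||% 0L), 1L)) "big"
            else "little"
  con <- file(bin_path, "rb"); on.exit(close(con))
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = !isTRUE(dt$unsigned))
  vals <- as.numeric(vals)
  # reshape: ENVI stores sample (column) fastest within each interleave block
  arr <- switch(interleave,
    bsq = aperm(array(vals, dim = c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(bands, cols, rows)), c(3, 2, 1))
  )
  kind <- if (identical(as.integer(hdr$reflectance %||% 0L), 1L))
    "reflectance" else "raw"
  hypercube(arr, wl, kind = kind)
}

#' @rdname read_envi
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  dt <- envi_dtypes[[as.character(data_type)]]
  if (is.null(dt)) {
    envi_format_error(sprintf("Unsupported ENVI data type %s.", data_type))
  }
  d <- dim(cube$data)
  flat <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1)))
  )
  con <- file(path, "wb")
  if (dt$what == "integer") {
    writeBin(as.integer(round(flat)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(flat), con, size = dt$size, endian = "little")
  }
  close(con)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("reflectance = %d", as.integer(cube$kind == "reflectance")),
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # fold multi-line { ... } blocks onto one line before key = value parsing
  collapsed <- character()
  buf <- ""
  in_block <- FALSE
  for (ln in lines) {
    if (!in_block) {
      buf <- ln
      if (grepl("\\{", ln) && !grepl("\\}", ln)) in_block <- TRUE
      else collapsed <- c(collapsed, buf)
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { in_block <- FALSE; collapsed <- c(collapsed, buf) }
    }
  }
  hdr <- list()
  for (ln in collapsed) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("^\\{", val)) {
      inner <- gsub("[{}]", "", val)
      parts <- trimws(strsplit(inner, ",")[[1]])
      nums <- suppressWarnings(as.numeric(parts))
      hdr[[key]] <- if (any(is.na(nums))) parts else nums
    } else {
      num <- suppressWarnings(as.numeric(val))
      hdr[[key]] <- if (is.na(num)) val else num
    }
  }
  hdr
}

#' Dark/white reflectance calibration
#'
#' Converts raw detector counts to reflectance with the standard two-point
#' correction `R = (I_raw - I_dark) / (I_white - I_dark)`, applied per pixel
#' and band. Dark and white references may be full cubes/arrays of the raw
#' cube's shape or single-line references; in either case they are averaged
#' over scan rows first, giving one reference spectrum per column, as is usual
#' for push-broom imagers.
#'
#' @param raw a raw-kind `hypercube`.
#' @param dark,white reference arrays (`rows x cols x bands` or
#'   `1 x cols x bands`) or `hypercube`s.
#' @return A reflectance-kind `hypercube`.
#' @export
calibrate <- function(raw, dark, white) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$kind != "raw") abort("`raw` cube is already calibrated.")
  d <- dim(raw$data)
  ref_mat <- function(x, nm) {
    if (inherits(x, "hypercube")) x <- x$data
    if (length(dim(x)) != 3 || dim(x)[2] != d[2] || dim(x)[3] != d[3]) {
      abort(sprintf("`%s` reference must be (rows) x %d x %d.", nm, d[2], d[3]))
    }
    apply(x, c(2, 3), mean)                      # cols x bands
  }
  dk <- ref_mat(dark, "dark")
  wt <- ref_mat(white, "white")
  denom <- wt - dk
  if (any(denom <= 0)) {
    bad <- which(denom <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Calibration error: white - dark <= 0 at column %d, band %d.",
      bad[1], bad[2]), class = "hsichemo_calibration_error")
  }
  out <- array(0, dim = d)
  for (b in seq_len(d[3])) {
    out[, , b] <- sweep(sweep(raw$data[, , b, drop = FALSE][, , 1],
                              2, dk[, b], "-"),
                        2, denom[, b], "/")
  }
  hypercube(out, raw$wavelengths, kind = "reflectance")
}

#' Regions of interest
#'
#' An ROI is either a rectangle (`roi_rect()`, 1-based inclusive row/column
#' bounds, matching R matrix indexing) or an explicit logical pixel mask
#' (`roi_mask()`).
#'
#' @param row0,row1,col0,col1 inclusive pixel bounds.
#' @param mask logical `rows x cols` matrix marking ROI pixels.
#' @return An `roi` object.
#' @export
roi_rect <- function(row0, col0, row1, col1) {
  if (row1 < row0 || col1 < col0) abort("Empty ROI rectangle.")
  structure(list(type = "rect", row0 = row0, col0 = col0,
                 row1 = row1, col1 = col1), class = "roi")
}

#' @rdname roi_rect
#' @export
roi_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (!is.logical(mask)) abort("ROI mask must be logical.")
  if (!any(mask)) abort("Empty ROI mask.")
  structure(list(type = "mask", mask = mask), class = "roi")
}

roi_to_mask <- function(roi, rows, cols) {
  stopifnot(inherits(roi, "roi"))
  if (roi$type == "mask") {
    if (!all(dim(roi$mask) == c(rows, cols))) {
      abort("ROI mask does not match the cube extent.")
    }
    return(roi$mask)
  }
  if (roi$row0 < 1 || roi$col0 < 1 || roi$row1 > rows || roi$col1 > cols) {
    abort("ROI rectangle exceeds the cube extent.")
  }
  m <- matrix(FALSE, rows, cols)
  m[roi$row0:roi$row1, roi$col0:roi$col1] <- TRUE
  m
}

#' Mean spectrum over a region of interest
#'
#' Averages a reflectance cube over the ROI pixels, one arithmetic mean per
#' band — the per-sample spectrum used throughout downstream modeling.
#'
#' @param cube a reflectance-kind `hypercube`.
#' @param roi an [roi_rect()] or [roi_mask()].
#' @param sample_id identifier attached to the resulting spectrum.
#' @return A tibble of class `spectrum_tbl` with columns `sample_id`,
#'   `wavelength` and `value`.
#' @export
roi_mean_spectrum <- function(cube, roi, sample_id = "sample") {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") {
    abort("ROI spectra are extracted from calibrated (reflectance) cubes.")
  }
  d <- dim(cube$data)
  m <- roi_to_mask(roi, d[1], d[2])
  if (!any(m)) abort("Empty ROI.")
  vals <- vapply(seq_len(d[3]),
                 function(b) mean(cube$data[, , b][m]), numeric(1))
  out <- tibble(sample_id = sample_id, wavelength = cube$wavelengths,
                value = vals)
  class(out) <- c("spectrum_tbl", class(out))
  out
}

#' Trim a spectral object to a wavelength window
#'
#' Retains exactly the bands whose wavelength lies in the closed interval
#' `[lo, hi]`, preserving order. Works on spectra datasets, single spectra and
#' hypercubes.
#'
#' @param x a `spectra_ds`, `spectrum_tbl` or `hypercube`.
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return Same type as `x`.
#' @export
trim_wavelengths <- function(x, lo, hi) {
  if (!(lo < hi)) abort("`lo` must be < `hi`.")
  UseMethod("trim_wavelengths")
}

#' @export
trim_wavelengths.spectra_ds <- function(x, lo, hi) {
  wl <- wavelengths(x)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) abort("No bands survive the wavelength trim.")
  if (all(keep)) return(x)
  restrict_dataset(x, which(keep),
                   method = sprintf("trim[%g,%g]", lo, hi))
}

#' @export
trim_wavelengths.spectrum_tbl <- function(x, lo, hi) {
  keep <- x$wavelength >= lo & x$wavelength <= hi
  if (!any(keep)) abort("No bands survive the wavelength trim.")
  x[keep, , drop = FALSE]
}

#' @export
trim_wavelengths.hypercube <- function(x, lo, hi) {
  keep <- x$wavelengths >= lo & x$wavelengths <= hi
  if (!any(keep)) abort("No bands survive the wavelength trim.")
  hypercube(x$data[, , keep, drop = FALSE], x$wavelengths[keep], kind = x$kind)
}

#' Collect ROI spectra from several cubes into a spectra dataset
#'
#' @param spectra list of `spectrum_tbl` objects on a shared wavelength axis.
#' @return A `spectra_ds` (reflectance).
#' @export
spectra_to_dataset <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  wl <- spectra[[1]]$wavelength
  X <- do.call(rbind, lapply(spectra, function(s) {
    if (!isTRUE(all.equal(s$wavelength, wl))) {
      abort("All spectra must share one wavelength axis.")
    }
    s$value
  }))
  spectra_dataset(X, wl,
                  sample_id = vapply(spectra, function(s) s$sample_id[1],
                                     character(1)),
                  space = "reflectance", provenance = "roi_mean")
}
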