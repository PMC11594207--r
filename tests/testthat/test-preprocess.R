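ds_from <- function(X, wl = NULL, space = "reflectance") {
  spectra_dataset(X, wl %||% seq(400, by = 10, length.out = ncol(X)),
                  space = space)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("absorbance conversion is log10(1/R)", {
  ds <- ds_from(matrix(c(1, 0.1, 0.5, 0.25), nrow = 1), wl = c(4, 5, 6, 7) * 100)
  ab <- to_absorbance(ds)
  expect_equal(unname(spectra_matrix(ab)[1, ]),
               c(0, 1, 0.30103, 0.60206), tolerance = 1e-5)
  expect_equal(spectra_space(ab), "absorbance")
  expect_error(to_absorbance(ab), "reflectance")
  expect_match(tail(provenance(ab), 1), "to_absorbance")
})

test_that("SNV standardizes rows and is idempotent and scale-invariant", {
  ds <- ds_from(matrix(c(1, 2, 3), nrow = 1), wl = c(400, 500, 600))
  out <- snv(ds)
  expect_equal(unname(spectra_matrix(out)[1, ]), c(-1, 0, 1))  # n-1 sd
  pop <- snv(ds, population_sd = TRUE)
  expect_equal(unname(spectra_matrix(pop)[1, ]),
               c(-1.22474, 0, 1.22474), tolerance = 1e-5)
  set.seed(1)
  X <- matrix(rnorm(60), 5, 12)
  dsX <- ds_from(X)
  expect_equal(spectra_matrix(snv(snv(dsX))), spectra_matrix(snv(dsX)),
               tolerance = 1e-12)
  expect_equal(spectra_matrix(snv(ds_from(3.5 * X))),
               spectra_matrix(snv(dsX)), tolerance = 1e-12)
  rs <- spectra_matrix(snv(dsX))
  expect_true(all(abs(rowMeans(rs)) < 1e-12))
  expect_true(all(abs(apply(rs, 1, sd) - 1) < 1e-12))
  expect_error(snv(ds_from(matrix(1, 2, 4))), "constant")
})

test_that("MSC inverts affine distortions of the reference", {
  set.seed(3)
  ref <- sort(runif(20))
  X <- rbind(ref, 2 * ref + 3, 0.5 * ref - 1)
  out <- spectra_matrix(msc(ds_from(X), reference = ref))
  for (i in 1:3) expect_equal(unname(out[i, ]), ref, tolerance = 1e-10)
  # two-band toy: x = [3,5], ref = [1,2] -> a = 1, b = 2 -> corrected [1,2]
  toy <- spectra_matrix(msc(ds_from(matrix(c(3, 5), 1), wl = c(400, 500)),
                            reference = c(1, 2)))
  expect_equal(unname(toy[1, ]), c(1, 2), tolerance = 1e-12)
  # default reference: a row equal to the column mean stays put
  Xm <- rbind(ref * 1.2 + 0.1, ref * 0.8 - 0.1)
  dsm <- ds_from(Xm)
  cm <- colMeans(Xm)
  corr <- spectra_matrix(msc(dsm))
  for (i in 1:2) {
    fit <- lm(Xm[i, ] ~ cm)
    expect_equal(unname(corr[i, ]),
                 unname((Xm[i, ] - coef(fit)[1]) / coef(fit)[2]),
                 tolerance = 1e-10)
  }
})

test_that("MSC pulls scatter-distorted duplicates back together", {
  improved <- sapply(1:10, function(s) {
    cfg <- synthetic_config(n_samples = 1, n_bands = 40, seed = s,
                            noise_sd = 0, scatter_sd = 0)
    base <- log10(1 / spectra_matrix(generate_spectra_dataset(cfg)$dataset))[1, ]
    set.seed(s + 50)
    m <- rnorm(6, 1, 0.1)
    X <- t(sapply(m, function(mi) mi * base + rnorm(40, 0, 1e-4)))
    d0 <- mean(dist(X))
    d1 <- mean(dist(spectra_matrix(msc(ds_from(X, space = "absorbance")))))
    d1 < d0
  })
  expect_gte(mean(improved), 0.9)
})

test_that("Savitzky-Golay derivatives annihilate low-order polynomials", {
  const <- ds_from(matrix(2.5, 2, 21))
  expect_true(all(abs(spectra_matrix(
    sg_filter(const, 7, 2, deriv = 1))) < 1e-10))
  lin <- ds_from(matrix(rep(seq_len(21), 2), 2, byrow = TRUE))
  d2 <- spectra_matrix(sg_filter(lin, 7, 3, deriv = 2))
  expect_true(all(abs(d2) < 1e-8))
  # first derivative of an index-linear row is its slope (per index step)
  d1 <- spectra_matrix(sg_filter(lin, 7, 3, deriv = 1))
  expect_true(all(abs(d1 - 1) < 1e-8))
})

test_that("SG smoothing with polyorder = window - 1 is the identity and the
           filter matches a local polynomial fit oracle", {
  set.seed(9)
  row <- rnorm(15)
  ds <- ds_from(matrix(row, 1))
  sm <- spectra_matrix(sg_filter(ds, 7, 6, deriv = 0))[1, ]
  expect_equal(unname(sm[4:12]), row[4:12], tolerance = 1e-8)
  # interior points of a plain smoothing pass match the explicit fit
  sm2 <- spectra_matrix(sg_filter(ds, 7, 3, deriv = 0))[1, ]
  for (i in 4:12) {
    expect_equal(unname(sm2[i]), oracle_sg_point(row[(i - 3):(i + 3)], 3, 0),
                 tolerance = 1e-10)
  }
  d1 <- spectra_matrix(sg_filter(ds, 7, 3, deriv = 1))[1, ]
  for (i in 4:12) {
    expect_equal(unname(d1[i]), oracle_sg_point(row[(i - 3):(i + 3)], 3, 1),
                 tolerance = 1e-10)
  }
})

test_that("SG parameter violations raise configuration errors", {
  ds <- ds_from(matrix(rnorm(40), 2, 20))
  expect_error(sg_filter(ds, 8, 3), class = "hsichemo_config_error")
  expect_error(sg_filter(ds, 5, 5), class = "hsichemo_config_error")
  expect_error(sg_filter(ds, 5, 1, deriv = 2), class = "hsichemo_config_error")
  expect_error(sg_filter(ds, 21, 3), class = "hsichemo_config_error")
})

test_that("mean centering stores reusable column means", {
  set.seed(4)
  X <- matrix(rnorm(50, mean = 3), 5, 10)
  ds <- ds_from(X)
  ctr <- mean_center(ds)
  expect_true(all(abs(colMeans(spectra_matrix(ctr))) < 1e-12))
  mu <- attr(ctr, "center_means")
  again <- apply_centering(ds, mu)
  expect_equal(spectra_matrix(again), spectra_matrix(ctr), tolerance = 1e-12)
  one <- apply_centering(ds_from(matrix(mu, 1)), mu)
  expect_true(all(abs(spectra_matrix(one)) < 1e-12))
})

test_that("transforms preserve shape, wavelengths, and provenance order", {
  sim <- generate_spectra_dataset(synthetic_config(n_samples = 6,
                                                   n_bands = 25, seed = 6))
  steps <- list("to_absorbance",
                list(fn = "sg_filter", window = 5, polyorder = 3, deriv = 2),
                "snv")
  out <- apply_pretreatments(sim$dataset, steps)
  expect_equal(dim(spectra_matrix(out)), dim(spectra_matrix(sim$dataset)))
  expect_equal(wavelengths(out), wavelengths(sim$dataset))
  expect_equal(tail(provenance(out), 3),
               c("to_absorbance", "sg_filter(window=5,polyorder=3,deriv=2)",
                 "snv"))
  expect_error(apply_pretreatments(sim$dataset, list("nope")), "Unknown")
})

test_that("pretreatment presets cover the standard method labels", {
  sim <- generate_spectra_dataset(synthetic_config(n_samples = 5,
                                                   n_bands = 30, seed = 1))
  for (m in c("raw", "msc", "snv", "1st", "2nd", "center", "sg")) {
    out <- apply_pretreatments(sim$dataset,
                               pretreatment_preset(m, window = 5))
    expect_equal(spectra_space(out), "absorbance")
    expect_equal(ncol(spectra_matrix(out)), 30)
  }
})
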