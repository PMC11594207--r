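test_that("the exponential-decline schedule hits its boundary conditions", {
  for (pn in list(c(225, 100), c(225, 50), c(60, 20))) {
    p <- pn[1]; N <- pn[2]
    expect_equal(edf_keep_count(1, N, p), p)
    expect_equal(edf_keep_count(N, N, p), 2L)
    counts <- edf_keep_count(seq_len(N), N, p)
    expect_true(all(diff(counts) <= 0))
  }
  # closed form at an interior run
  a <- (225 / 2)^(1 / 99); k <- log(225 / 2) / 99
  expect_equal(edf_keep_count(38, 100, 225),
               max(2L, as.integer(round(a * exp(-k * 38) * 225))))
  expect_error(edf_keep_count(1, 1, 10), ">= 2")
  expect_error(edf_keep_count(0, 10, 10), "1..N")
})

scaled_2nd <- function(seed) {
  sim <- generate_spectra_dataset(scaled_synthetic_config(seed = seed))
  list(ds = apply_pretreatments(sim$dataset,
                                pretreatment_preset("2nd", window = 5)),
       truth = sim$truth)
}

test_that("CARS traces decay monotonically to 2 bands and are seeded", {
  prep <- scaled_2nd(3)
  sp <- spxy_split(spectra_matrix(prep$ds), prep$ds$ssc)
  Xc <- spectra_matrix(prep$ds)[sp$calibration, ]
  yc <- prep$ds$ssc[sp$calibration]
  cfg <- cars_config(n_runs = 30, cv_folds = 5, max_lv = 5, seed = 21)
  tr <- cars_select(Xc, yc, cfg)
  expect_true(all(diff(tr$kept_count_per_run) <= 0))
  expect_equal(tail(tr$kept_count_per_run, 1), 2L)
  expect_equal(tr$selected_indices, tr$subset_per_run[[tr$best_run]])
  expect_equal(tr$best_run, which.min(tr$score_per_run))
  tr2 <- cars_select(Xc, yc, cfg)
  expect_identical(tr$selected_indices, tr2$selected_indices)
  expect_identical(tr$score_per_run, tr2$score_per_run)
})

test_that("CARS recovers planted SSC bands on most seeds", {
  hits <- sapply(1:6, function(s) {
    prep <- scaled_2nd(s)
    sp <- spxy_split(spectra_matrix(prep$ds), prep$ds$ssc)
    tr <- cars_select(spectra_matrix(prep$ds)[sp$calibration, ],
                      prep$ds$ssc[sp$calibration],
                      cars_config(n_runs = 50, cv_folds = 10, max_lv = 5,
                                  seed = s + 200))
    any(prep$truth$informative_indices_ssc %in% tr$selected_indices)
  })
  expect_gte(sum(hits), 5)
})

test_that("frog probabilities are containment frequencies with the strict
           threshold rule", {
  prep <- scaled_2nd(4)
  sp <- spxy_split(spectra_matrix(prep$ds), prep$ds$ssc)
  Xc <- spectra_matrix(prep$ds)[sp$calibration, ]
  yc <- prep$ds$ssc[sp$calibration]
  cfg <- frog_config(n_iterations = 200, q_init = 3, n_lv = 3,
                     cv_folds = 4, seed = 5)
  tr <- frog_select(Xc, yc, cfg)
  expect_true(all(tr$selection_probability >= 0 &
                    tr$selection_probability <= 1))
  expect_gt(max(tr$selection_probability), 0)
  expect_equal(tr$selected_indices,
               which(tr$selection_probability > 0.1))
  # strict inequality: a threshold of 1 selects nothing
  cfg1 <- frog_config(n_iterations = 200, q_init = 3, n_lv = 3,
                      cv_folds = 4, threshold = 1, seed = 5)
  expect_length(frog_select(Xc, yc, cfg1)$selected_indices, 0)
  # seeded determinism
  tr2 <- frog_select(Xc, yc, cfg)
  expect_identical(tr$selection_probability, tr2$selection_probability)
  expect_true(frog_select(Xc[, 1:10], yc,
                          frog_config(n_iterations = 50, q_init = 2,
                                      n_lv = 2, cv_folds = 3,
                                      seed = 1))$low_iteration_warning)
  expect_error(frog_select(Xc[, 1:2], yc,
                           frog_config(q_init = 5, seed = 1)), "exceeds")
})

test_that("band relabeling does not change which bands the frog favors", {
  # The walk is chaotic in floating point (a single accept decision at the
  # rounding limit diverges the trajectory), so exact equivariance under a
  # column permutation is not attainable; the favored bands must agree.
  prep <- scaled_2nd(6)
  sp <- spxy_split(spectra_matrix(prep$ds), prep$ds$ssc)
  Xc <- spectra_matrix(prep$ds)[sp$calibration, 31:50]
  yc <- prep$ds$ssc[sp$calibration]
  cfg <- frog_config(n_iterations = 400, q_init = 3, n_lv = 3,
                     cv_folds = 4, seed = 9)
  base <- frog_select(Xc, yc, cfg)$selection_probability
  set.seed(31)
  perm <- sample(20)
  permuted <- frog_select(Xc[, perm], yc, cfg)$selection_probability
  # permutation-aware comparison: column j of the permuted matrix is
  # original column perm[j]
  expect_true(which.max(permuted) %in%
                order(base[perm], decreasing = TRUE)[1:3])
  expect_gt(cor(base[perm], permuted, method = "spearman"), 0.5)
})

test_that("frog favors planted potassium bands", {
  wins <- sapply(1:5, function(s) {
    prep <- scaled_2nd(s)
    sp <- spxy_split(spectra_matrix(prep$ds), prep$ds$k)
    tr <- frog_select(spectra_matrix(prep$ds)[sp$calibration, ],
                      prep$ds$k[sp$calibration],
                      frog_config(n_iterations = 800, q_init = 3, n_lv = 3,
                                  cv_folds = 5, seed = s + 300))
    pk <- prep$truth$informative_indices_k
    mean(tr$selection_probability[pk]) >
      mean(tr$selection_probability[-pk])
  })
  expect_gte(sum(wins), 4)
})

test_that("restrict_dataset subsets bands and logs the retained fraction", {
  sim <- generate_spectra_dataset(synthetic_config(n_samples = 4, seed = 1))
  ds <- sim$dataset
  all_idx <- seq_along(wavelengths(ds))
  same <- restrict_dataset(ds, all_idx)
  expect_equal(spectra_matrix(same), spectra_matrix(ds))
  one <- restrict_dataset(ds, 1)
  expect_equal(ncol(spectra_matrix(one)), 1)
  expect_equal(wavelengths(one), wavelengths(ds)[1])
  sel <- restrict_dataset(ds, 1:69, method = "cars")
  expect_match(tail(provenance(sel), 1), "69/225 bands \\(30.67%\\)",
               fixed = FALSE)
  expect_error(restrict_dataset(ds, integer(0)), "nonempty")
  expect_error(restrict_dataset(ds, c(1, 1)), "unique")
  expect_error(restrict_dataset(ds, 9999), "Invalid band index")
})
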