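test_that("SPXY picks the extremes of a collinear set and is deterministic", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  y <- c(0, 1, 2)
  sp <- spxy_split(X, y, ratio = 2 / 3)
  expect_setequal(sp$calibration, c(1, 3))
  expect_equal(sp$prediction, 2)
  sp2 <- spxy_split(X, y, ratio = 2 / 3)
  expect_identical(sp$calibration, sp2$calibration)
})

test_that("SPXY matches the explicit greedy oracle on small sets", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rnorm(n)
    n_cal <- round(n * 2 / 3)
    sp <- spxy_split(X, y, ratio = 2 / 3)
    expect_equal(sort(sp$calibration), sort(oracle_spxy(X, y, n_cal)),
                 info = paste("seed", s))
  }
})

test_that("SPXY guards degenerate inputs", {
  expect_error(spxy_split(matrix(1, 5, 3), rep(2, 5)), "spread")
  expect_error(spxy_split(matrix(1, 5, 3), 1:5), "identical")
  expect_error(spxy_split(matrix(rnorm(4), 2, 2), 1:2), "at least 3")
})

test_that("PLS1 with one predictor reduces to the least-squares line", {
  set.seed(7)
  x <- rnorm(20); y <- 2 + 3 * x + rnorm(20, 0, 0.1)
  m <- fit_pls(matrix(x), y, max_lv = 1, cv_folds = 5)
  ols <- lm(y ~ x)
  expect_equal(predict_pls(m, matrix(x)), unname(fitted(ols)),
               tolerance = 1e-8)
})

test_that("exact linear maps are interpolated at full rank", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + 4
  m <- fit_pls(X, y, max_lv = 3, cv_folds = 5)
  expect_lt(evaluate_regression(y, predict_pls(m, X))$rmse, 1e-8)
})

test_that("coefficients match an independent loop-explicit NIPALS oracle", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
    core <- hsichemo:::nipals_pls_core(X, matrix(y), 2)
    b <- hsichemo:::pls_coefficients(core)[, 1]
    orc <- oracle_nipals_pls1(X, y, 2)
    expect_equal(unname(b), unname(orc$b), tolerance = 1e-6,
                 info = paste("seed", s))
  }
})

test_that("score orthogonality and coefficient/latent route agreement hold", {
  set.seed(12)
  X <- matrix(rnorm(80), 16, 5)
  y <- rnorm(16)
  core <- hsichemo:::nipals_pls_core(X, matrix(y), 4)
  G <- crossprod(core$T)
  expect_true(all(abs(G[upper.tri(G)]) < 1e-8))
  # latent-route prediction: scores of new data times y-loadings
  Xc <- sweep(X, 2, core$x_mean)
  R <- core$W %*% solve(crossprod(core$P, core$W))
  y_lat <- drop(Xc %*% R %*% t(core$Q)) + core$y_mean
  y_coef <- hsichemo:::pls_predict_core(core, X)[, 1]
  expect_equal(y_lat, y_coef, tolerance = 1e-8)
})

test_that("full-rank PLS reproduces the minimum-norm least-squares fit", {
  set.seed(13)
  X <- matrix(rnorm(48), 12, 4)
  y <- rnorm(12)
  core <- hsichemo:::nipals_pls_core(X, matrix(y), 4)
  b <- hsichemo:::pls_coefficients(core)[, 1]
  expect_equal(unname(b), unname(oracle_minnorm_ls(X, y)), tolerance = 1e-6)
})

test_that("the RMSECV curve matches a brute-force refit-per-fold oracle", {
  set.seed(14)
  X <- matrix(rnorm(108), 18, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(18, 0, 0.3)
  k <- 3; A <- 4
  m <- fit_pls(X, y, max_lv = A, cv_folds = k)
  folds <- ((seq_len(18) - 1) %% k) + 1
  rmsecv <- sapply(seq_len(A), function(a) {
    press <- 0
    for (f in 1:k) {
      tr <- folds != f
      core <- hsichemo:::nipals_pls_core(X[tr, , drop = FALSE], y[tr], a)
      yh <- hsichemo:::pls_predict_core(core, X[!tr, , drop = FALSE])[, 1]
      press <- press + sum((y[!tr] - yh)^2)
    }
    sqrt(press / 18)
  })
  expect_equal(m$rmsecv, rmsecv, tolerance = 1e-10)
  expect_equal(m$n_lv, which.min(rmsecv))
})

test_that("prediction at the calibration mean returns the response mean", {
  set.seed(15)
  X <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  m <- fit_pls(X, y, max_lv = 3, cv_folds = 4)
  expect_equal(predict_pls(m, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
  expect_error(predict_pls(m, matrix(0, 2, 4)), "expects 5 bands")
  expect_error(fit_pls(X, rep(1, 12)), "zero variance")
})

test_that("PLS-DA separates separable classes and ties go to the lower
           class index", {
  set.seed(16)
  X <- rbind(matrix(rnorm(40, -2), 10, 4), matrix(rnorm(40, 2), 10, 4))
  labels <- rep(c("a", "b"), each = 10)
  m <- fit_plsda(X, labels, max_lv = 3, cv_folds = 5)
  acc <- evaluate_classification(labels, predict_plsda(m, X))$accuracy
  expect_equal(acc, 100)
  tied <- matrix(c(0.5, 0.5, 0.2, 0.9), 2, 2,
                 dimnames = list(NULL, c("a", "b")))
  expect_equal(hsichemo:::plsda_decide(tied, c("a", "b")), c("a", "b"))
  expect_error(fit_plsda(X, rep("a", 20)), "2 classes")
})

test_that("PLS-DA recovers planted class structure at high SNR", {
  accs <- sapply(1:10, function(s) {
    sim <- generate_spectra_dataset(scaled_synthetic_config(seed = s))
    ds <- apply_pretreatments(sim$dataset,
                              pretreatment_preset("2nd", window = 5))
    sp <- spxy_split(spectra_matrix(ds),
                     as.numeric(factor(ds$origin_class)))
    m <- fit_plsda(spectra_matrix(ds)[sp$calibration, ],
                   ds$origin_class[sp$calibration],
                   max_lv = 10, cv_folds = 5)
    evaluate_classification(
      ds$origin_class[sp$prediction],
      predict_plsda(m, spectra_matrix(ds)[sp$prediction, ]))$accuracy
  })
  expect_gte(mean(accs), 95)
})

test_that("random forests memorize separable data and are seed-stable", {
  set.seed(17)
  X <- rbind(matrix(rnorm(20, -3), 5, 4), matrix(rnorm(20, 3), 5, 4))
  labels <- rep(c("dom", "imp"), each = 5)
  m <- fit_rft(X, labels, n_trees = 200, seed = 42)
  expect_equal(evaluate_classification(labels, predict_rft(m, X))$accuracy,
               100)
  m2 <- fit_rft(X, labels, n_trees = 200, seed = 42)
  expect_identical(predict_rft(m, X), predict_rft(m2, X))
  expect_error(fit_rft(X, rep("dom", 10)), "2 classes")
})

test_that("random forests on permuted labels sit near the majority rate", {
  gaps <- sapply(1:10, function(s) {
    sim <- generate_spectra_dataset(
      synthetic_config(n_samples = 60, n_bands = 30, seed = s))
    ds <- to_absorbance(sim$dataset)
    set.seed(s + 70)
    lab <- sample(ds$origin_class)
    idx <- 1:40
    m <- fit_rft(spectra_matrix(ds)[idx, ], lab[idx], n_trees = 200,
                 seed = s)
    acc <- evaluate_classification(
      lab[-idx], predict_rft(m, spectra_matrix(ds)[-idx, ]))$accuracy
    maj <- 100 * max(table(lab[idx])) / 40
    acc - maj
  })
  expect_lte(abs(mean(gaps)), 10)
})

test_that("evaluation metrics follow their definitions", {
  perf <- evaluate_regression(c(1, 2, 3), c(1, 2, 3), "calibration")
  expect_equal(perf$r2, 1)
  expect_equal(perf$rmse, 0)
  worked <- evaluate_regression(c(0, 2), c(1, 1))
  expect_equal(worked$rmse, 1)     # SS_res = 2 over n = 2
  expect_equal(worked$r2, 0)       # SS_res = SS_tot = 2
  expect_equal(evaluate_classification(c("a", "a", "b", "b"),
                                       c("a", "a", "b", "a"))$accuracy, 75)
  expect_error(evaluate_regression(c(1, 1), c(1, 2)), "Zero-variance")
  expect_error(evaluate_regression(1:3, 1:2), "mismatch")
})
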