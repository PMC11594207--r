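# Shared settings for the scaled-down benchmark experiments: 99 samples on a
# 60-band grid, second-derivative pretreatment with the window matched to the
# planted peaks' FWHM, selector latent-variable caps matched to the
# simulation's component rank.

analogue_pretreated <- function(seed) {
  sim <- generate_spectra_dataset(scaled_synthetic_config(seed = seed))
  list(ds = apply_pretreatments(
    sim$dataset, pretreatment_preset("2nd", window = 5, polyorder = 3)),
    truth = sim$truth)
}

analogue_cars_config <- function(seed) {
  cars_config(n_runs = 100, cv_folds = 10, max_lv = 5, seed = seed)
}

analogue_frog_config <- function(seed, task = "regression") {
  if (task == "regression") {
    frog_config(n_iterations = 1500, q_init = 3, n_lv = 3, cv_folds = 5,
                seed = seed)
  } else {
    frog_config(n_iterations = 1000, q_init = 2, n_lv = 3, cv_folds = 5,
                seed = seed)
  }
}

analogue_r2p <- function(X_cal, y_cal, X_pred, y_pred, idx = NULL) {
  if (!is.null(idx)) {
    X_cal <- X_cal[, idx, drop = FALSE]
    X_pred <- X_pred[, idx, drop = FALSE]
  }
  m <- fit_pls(X_cal, y_cal, max_lv = 10, cv_folds = 10)
  evaluate_regression(y_pred, predict_pls(m, X_pred), "prediction")$r2
}
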