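# Wavelength selection: CARS and random frog --------------------------------

resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# |coefficient| magnitude per retained band, from a PLS(-DA) fit
coef_magnitude <- function(X, y, nlv, task) {
  if (task == "classification") {
    enc <- one_hot(y)
    core <- nipals_pls_core(X, enc$Y, nlv)
    B <- pls_coefficients(core)
    sqrt(rowSums(B^2))
  } else {
    core <- nipals_pls_core(X, matrix(as.numeric(y)), nlv)
    abs(pls_coefficients(core)[, 1])
  }
}

# k-fold CV score on a band subset: RMSECV for regression, 1 - accuracy for
# classification (so "minimize" applies to both tasks). The latent-variable
# count is optimized per subset (best score over 1..nlv), as is standard when
# comparing subsets of very different sizes.
cv_subset_score <- function(X, y, folds, nlv, task) {
  n <- nrow(X)
  if (task == "classification") {
    enc <- one_hot(y)
    lab <- as.character(y)
    correct <- rep(0, nlv)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      core <- nipals_pls_core(X[tr, , drop = FALSE],
                              enc$Y[tr, , drop = FALSE], nlv)
      for (a in seq_len(nlv)) {
        sc <- pls_predict_core(core, X[!tr, , drop = FALSE],
                               nlv = min(a, core$n_lv))
        correct[a] <- correct[a] +
          sum(plsda_decide(sc, enc$levels) == lab[!tr])
      }
    }
    1 - max(correct) / n
  } else {
    y <- as.numeric(y)
    press <- rep(0, nlv)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      core <- nipals_pls_core(X[tr, , drop = FALSE], y[tr], nlv)
      for (a in seq_len(nlv)) {
        yh <- pls_predict_core(core, X[!tr, , drop = FALSE],
                               nlv = min(a, core$n_lv))[, 1]
        press[a] <- press[a] + sum((y[!tr] - yh)^2)
      }
    }
    sqrt(min(press) / n)
  }
}

subset_nlv <- function(max_lv, q, n, folds) {
  train_min <- n - max(tabulate(folds))
  max(1L, min(max_lv, q, train_min - 1L))
}

#' Configuration for CARS wavelength selection
#'
#' Competitive adaptive reweighted sampling runs `n_runs` sampling rounds; in
#' each round a Monte-Carlo subset of calibration rows is drawn, a PLS model
#' ranks the surviving bands by absolute regression coefficient, an
#' exponentially decreasing schedule forces the weakest bands out, adaptive
#' reweighted sampling (weighted draws with replacement) competitively prunes
#' the remainder, and the retained subset is scored by cross-validation. The
#' subset with the best score wins.
#'
#' @param n_runs number of sampling runs `N` (>= 2). Typical values: 100 for
#'   SSC-style regression, 50 for potassium and origin tasks.
#' @param n_monte_carlo accepted for forward compatibility with
#'   configurations that state a Monte-Carlo simulation count separately from
#'   the run count; the selector's single run loop does not use it.
#' @param cv_folds cross-validation folds for subset scoring (10, 15 and 8
#'   are typical for the SSC, potassium and origin tasks).
#' @param mc_sample_fraction fraction of calibration rows drawn per run.
#' @param max_lv cap on PLS latent variables inside the selector.
#' @param seed integer seed.
#' @return A list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 100, n_monte_carlo = 1000, cv_folds = 10,
                        mc_sample_fraction = 0.8, max_lv = 10, seed = 1L) {
  if (n_runs < 2) abort("`n_runs` must be >= 2.",
                        class = "hsichemo_config_error")
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.",
                          class = "hsichemo_config_error")
  if (mc_sample_fraction <= 0 || mc_sample_fraction > 1) {
    abort("`mc_sample_fraction` must lie in (0, 1].",
          class = "hsichemo_config_error")
  }
  structure(list(n_runs = as.integer(n_runs),
                 n_monte_carlo = as.integer(n_monte_carlo),
                 cv_folds = as.integer(cv_folds),
                 mc_sample_fraction = mc_sample_fraction,
                 max_lv = as.integer(max_lv), seed = as.integer(seed)),
            class = "cars_config")
}

#' Exponential-decline keep count for CARS
#'
#' The forced-deletion schedule keeps a fraction `r_i = a * exp(-k * i)` of
#' the `p` bands at run `i`, with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)` fixed by the boundary conditions: all `p` bands
#' survive run 1 and exactly 2 survive run `N`. The keep count is
#' `round(r_i * p)`, floored at 2.
#'
#' @param i run index, `1..N`.
#' @param N total number of runs (>= 2).
#' @param p number of bands (>= 2).
#' @return Integer keep count.
#' @export
#' @examples
#' edf_keep_count(1, 100, 225)   # 225
#' edf_keep_count(100, 100, 225) # 2
edf_keep_count <- function(i, N, p) {
  if (N < 2) abort("`N` must be >= 2.")
  if (p < 2) abort("`p` must be >= 2.")
  if (any(i < 1 | i > N)) abort("`i` must lie in 1..N.")
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  pmax(2L, as.integer(round(a * exp(-k * i) * p)))
}

#' Run CARS wavelength selection
#'
#' @param X calibration matrix (n x p) or `spectra_ds`.
#' @param y response: numeric for `task = "regression"`, labels for
#'   `task = "classification"` (for a `spectra_ds`, the column name).
#' @param config a [cars_config()].
#' @param task `"regression"` or `"classification"`; classification subsets
#'   are scored by `1 - CV accuracy` so that score minimization applies to
#'   both tasks.
#' @return A `cars_trace` with per-run kept counts, scores and subsets, the
#'   best run and the selected band indices (1-based).
#' @export
cars_select <- function(X, y, config = cars_config(),
                        task = c("regression", "classification")) {
  task <- match.arg(task)
  if (is_spectra_dataset(X)) {
    stopifnot(is.character(y))
    ds <- X; y <- ds[[y]]; X <- spectra_matrix(ds)
  }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) abort("CARS needs at least 2 bands.")
  cfg <- config
  set.seed(cfg$seed)
  folds <- venetian_folds(n, cfg$cv_folds)
  m_rows <- max(2L, round(cfg$mc_sample_fraction * n))

  pool <- seq_len(p)
  kept_count <- integer(cfg$n_runs)
  score <- numeric(cfg$n_runs)
  subsets <- vector("list", cfg$n_runs)
  truncated <- FALSE
  for (i in seq_len(cfg$n_runs)) {
    rows <- sort(resample(seq_len(n), m_rows))
    nlv_fit <- max(1L, min(cfg$max_lv, length(pool), length(rows) - 1L))
    w <- coef_magnitude(X[rows, pool, drop = FALSE], subset_y(y, rows),
                        nlv_fit, task)
    # (2) forced deletion: exponential-decline keep count
    K <- min(edf_keep_count(i, cfg$n_runs, p), length(pool))
    top <- order(w, decreasing = TRUE)[seq_len(K)]
    pool_k <- pool[top]; w_k <- w[top]
    # (3) adaptive reweighted sampling: p weighted draws with replacement
    # (drawing the original band count keeps the EDF schedule in charge of
    # the decay; the competitive step then prunes only low-weight bands)
    if (all(w_k <= 0)) w_k <- rep(1, length(w_k))
    drawn <- unique(resample(seq_along(pool_k), p, replace = TRUE,
                             prob = w_k))
    if (length(drawn) < 2) {
      drawn <- unique(c(drawn, order(w_k, decreasing = TRUE)))[1:2]
    }
    pool <- sort(pool_k[drawn])
    if (length(pool) < 2) { truncated <- TRUE; break }
    # (4) CV score of the retained subset on all calibration rows
    nlv_cv <- subset_nlv(cfg$max_lv, length(pool), n, folds)
    score[i] <- cv_subset_score(X[, pool, drop = FALSE], y, folds, nlv_cv,
                                task)
    kept_count[i] <- length(pool)
    subsets[[i]] <- pool
  }
  done <- which(kept_count > 0)
  best <- done[which.min(score[done])]
  structure(list(
    kept_count_per_run = kept_count[done],
    score_per_run = score[done],
    subset_per_run = subsets[done],
    best_run = match(best, done),
    selected_indices = subsets[[best]],
    task = task, truncated = truncated,
    config = cfg, p = p
  ), class = "cars_trace")
}

subset_y <- function(y, rows) if (is.matrix(y)) y[rows, , drop = FALSE] else y[rows]

#' @export
print.cars_trace <- function(x, ...) {
  cat(sprintf(
    "# CARS trace: %d runs, best run %d, %d of %d bands selected (%.2f%%)\n",
    length(x$kept_count_per_run), x$best_run, length(x$selected_indices),
    x$p, retained_fraction_pct(length(x$selected_indices), x$p)))
  invisible(x)
}

#' @export
tidy.cars_trace <- function(x, ...) {
  tibble(run = seq_along(x$kept_count_per_run),
         kept_count = x$kept_count_per_run,
         score = x$score_per_run,
         best = seq_along(x$kept_count_per_run) == x$best_run)
}

#' Plot a CARS selection trace
#'
#' Two stacked panels over the sampling runs: the number of retained bands
#' (the exponential-decline schedule followed by competitive pruning) and the
#' cross-validation score, with the winning run marked.
#'
#' @param object a `cars_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cars_trace <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("kept_count", "score"),
                              names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_run, linetype = 2) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Sampling run", y = NULL) +
    ggplot2::theme_minimal()
}

#' Configuration for random-frog wavelength selection
#'
#' Random frog walks through band subsets: from the current subset a
#' candidate of Normally perturbed size is proposed (weakest bands dropped or
#' strongest candidates added by PLS coefficient magnitude), scored by
#' cross-validation, and accepted outright when better or with probability
#' `accept_factor * (score_old / score_new)` when worse. A band's selection
#' probability is the fraction of iterations whose accepted subset contains
#' it; bands above `threshold` are selected.
#'
#' @param n_iterations number of iterations (5000 is typical for
#'   quantitative work, 10000 for discrimination; below 100 a warning is
#'   recorded in the trace).
#' @param q_init initial subset size `Q` (3 quantitative / 2 discrimination
#'   are typical).
#' @param n_lv PLS components used when scoring subsets (10 / 15 typical).
#' @param variance_factor spread of the proposal size:
#'   `q* ~ Normal(Q_current, variance_factor * Q_current)`.
#' @param accept_factor probability scale for accepting worse subsets, in
#'   (0, 1].
#' @param threshold selection-probability cutoff (strict `>`), in (0, 1).
#' @param cv_folds folds for subset scoring.
#' @param seed integer seed.
#' @return A list of class `frog_config`.
#' @export
frog_config <- function(n_iterations = 5000, q_init = 3, n_lv = 10,
                        variance_factor = 0.3, accept_factor = 0.1,
                        threshold = 0.1, cv_folds = 5, seed = 1L) {
  cfg_err <- function(msg) abort(msg, class = "hsichemo_config_error")
  if (q_init < 1) cfg_err("`q_init` must be >= 1.")
  if (threshold <= 0 || threshold > 1) {
    cfg_err("`threshold` must lie in (0, 1].")
  }
  if (accept_factor <= 0 || accept_factor > 1) {
    cfg_err("`accept_factor` must lie in (0, 1].")
  }
  if (cv_folds < 2) cfg_err("`cv_folds` must be >= 2.")
  structure(list(n_iterations = as.integer(n_iterations),
                 q_init = as.integer(q_init), n_lv = as.integer(n_lv),
                 variance_factor = variance_factor,
                 accept_factor = accept_factor, threshold = threshold,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "frog_config")
}

#' Run random-frog wavelength selection
#'
#' @inheritParams cars_select
#' @param config a [frog_config()].
#' @return A `frog_trace` with per-band selection probabilities, the
#'   subset-size path and the selected indices (probability strictly above
#'   the threshold).
#' @export
frog_select <- function(X, y, config = frog_config(),
                        task = c("regression", "classification")) {
  task <- match.arg(task)
  if (is_spectra_dataset(X)) {
    stopifnot(is.character(y))
    ds <- X; y <- ds[[y]]; X <- spectra_matrix(ds)
  }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  cfg <- config
  if (cfg$q_init > p) abort("`q_init` exceeds the number of bands.")
  warning_low_iter <- cfg$n_iterations < 100
  set.seed(cfg$seed)
  folds <- venetian_folds(n, cfg$cv_folds)
  score_of <- function(sub) {
    nlv <- subset_nlv(cfg$n_lv, length(sub), n, folds)
    cv_subset_score(X[, sub, drop = FALSE], y, folds, nlv, task)
  }
  rank_mag <- function(sub) {
    nlv <- subset_nlv(cfg$n_lv, length(sub), n, folds)
    coef_magnitude(X[, sub, drop = FALSE], y, nlv, task)
  }

  V <- sort(resample(seq_len(p), cfg$q_init))
  score_V <- score_of(V)
  contain <- integer(p)
  sizes <- integer(cfg$n_iterations)
  for (it in seq_len(cfg$n_iterations)) {
    q_cur <- length(V)
    q_star <- max(1L, min(p, as.integer(round(
      rnorm(1, q_cur, cfg$variance_factor * q_cur)))))
    if (q_star < q_cur) {
      mag <- rank_mag(V)
      Vc <- sort(V[order(mag, decreasing = TRUE)[seq_len(q_star)]])
    } else if (q_star > q_cur) {
      outside <- setdiff(seq_len(p), V)
      pool <- resample(outside, min(length(outside),
                                    max(q_star - q_cur, 2L) * 3L))
      sup <- sort(c(V, pool))
      mag <- rank_mag(sup)
      Vc <- sort(sup[order(mag, decreasing = TRUE)[seq_len(
        min(q_star, length(sup)))]])
    } else {
      Vc <- V
    }
    score_c <- if (identical(Vc, V)) score_V else score_of(Vc)
    accept <- score_c <= score_V ||
      runif(1) < min(1, cfg$accept_factor * (score_V / max(score_c, 1e-12)))
    if (accept) { V <- Vc; score_V <- score_c }
    contain[V] <- contain[V] + 1L
    sizes[it] <- length(V)
  }
  prob <- contain / cfg$n_iterations
  structure(list(
    selection_probability = prob,
    subset_size_per_iteration = sizes,
    selected_indices = which(prob > cfg$threshold),
    task = task, config = cfg, p = p,
    low_iteration_warning = warning_low_iter
  ), class = "frog_trace")
}

#' @export
print.frog_trace <- function(x, ...) {
  cat(sprintf(
    "# Random-frog trace: %d iterations, %d of %d bands above threshold %.2f\n",
    x$config$n_iterations, length(x$selected_indices), x$p,
    x$config$threshold))
  if (x$low_iteration_warning) {
    cat("# Warning: fewer than 100 iterations; probabilities are unstable.\n")
  }
  invisible(x)
}

#' @export
tidy.frog_trace <- function(x, ...) {
  tibble(band = seq_len(x$p),
         selection_probability = x$selection_probability,
         selected = seq_len(x$p) %in% x$selected_indices)
}

#' Plot random-frog selection probabilities per band
#'
#' @param object a `frog_trace`.
#' @param wavelengths optional wavelength axis for the x scale.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.frog_trace <- function(object, wavelengths = NULL, ...) {
  df <- tidy(object)
  df$x <- wavelengths %||% df$band
  xlab <- if (is.null(wavelengths)) "Band index" else "Wavelength (nm)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x,
                                   y = .data$selection_probability)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x, yend = 0,
                                       colour = .data$selected)) +
    ggplot2::geom_hline(yintercept = object$config$threshold, linetype = 2) +
    ggplot2::labs(x = xlab, y = "Selection probability") +
    ggplot2::theme_minimal()
}

#' Retained-band fraction, in percent
#'
#' @param n_kept,n_total band counts.
#' @return Percentage rounded to two decimals (e.g. 69 of 225 -> 30.67).
#' @export
retained_fraction_pct <- function(n_kept, n_total) {
  round(100 * n_kept / n_total, 2)
}

#' Restrict a spectra dataset to selected bands
#'
#' Column-subsets the spectral block (order-preserving) and records the
#' selection and retained fraction in the provenance log.
#'
#' @param ds a `spectra_ds`.
#' @param indices unique, valid band indices (1-based).
#' @param method label recorded in provenance (e.g. `"cars"`, `"frog"`).
#' @return The restricted `spectra_ds`.
#' @export
restrict_dataset <- function(ds, indices, method = "manual") {
  stopifnot(is_spectra_dataset(ds))
  p <- length(wavelengths(ds))
  indices <- as.integer(indices)
  if (length(indices) == 0) abort("`indices` must be nonempty.")
  if (anyDuplicated(indices)) abort("`indices` must be unique.")
  if (any(indices < 1 | indices > p)) {
    abort(sprintf("Invalid band index; valid range is 1..%d.", p))
  }
  indices <- sort(indices)
  X <- spectra_matrix(ds)[, indices, drop = FALSE]
  step <- sprintf("select[%s]: kept %d/%d bands (%.2f%%)",
                  method, length(indices), p,
                  retained_fraction_pct(length(indices), p))
  spectra_dataset(
    X, wavelengths(ds)[indices], sample_id = ds$sample_id,
    ssc = if (all(is.na(ds$ssc))) NULL else ds$ssc,
    k = if (all(is.na(ds$k))) NULL else ds$k,
    origin_class = if (all(is.na(ds$origin_class))) NULL else ds$origin_class,
    space = spectra_space(ds),
    provenance = c(provenance(ds), step)
  )
}
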