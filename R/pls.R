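# NIPALS partial least squares --------------------------------------------
#
# The core fitting routine handles PLS1 (single response, direct weight
# computation) and PLS2 (multi-response, iterative NIPALS inner loop) on
# column-centered X and Y. Regression coefficients in original band space are
# B = W (P'W)^-1 Q', so predictions can take either the latent route
# (scores x y-loadings) or the coefficient route.

nipals_pls_core <- function(X, Y, nlv, max_iter = 500, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  nlv <- min(nlv, p, n - 1)
  W <- matrix(0, p, nlv); P <- matrix(0, p, nlv)
  Q <- matrix(0, m, nlv); Tm <- matrix(0, n, nlv)
  a <- 0
  for (h in seq_len(nlv)) {
    if (sum(Xc^2) < 1e-24) break
    if (m == 1) {
      w <- crossprod(Xc, Yc)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-24) break
      w <- w / nw
      tt <- Xc %*% w
      qq <- crossprod(Yc, tt)[, 1] / sum(tt^2)
    } else {
      u <- Yc[, which.max(colSums(Yc^2))]
      w_old <- rep(0, p)
      converged <- FALSE
      degenerate <- FALSE
      for (it in seq_len(max_iter)) {
        w <- crossprod(Xc, u)[, 1]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-24) { degenerate <- TRUE; break }
        w <- w / nw
        tt <- Xc %*% w
        qq <- crossprod(Yc, tt)[, 1] / sum(tt^2)
        u <- Yc %*% qq / sum(qq^2)
        if (sqrt(sum((w - w_old)^2)) < tol) { converged <- TRUE; break }
        w_old <- w
      }
      if (degenerate) break
      if (!converged) {
        abort("NIPALS failed to converge within 500 iterations.",
              class = "hsichemo_convergence_error")
      }
    }
    pp <- crossprod(Xc, tt)[, 1] / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, qq)
    a <- a + 1
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq; Tm[, a] <- tt
  }
  if (a == 0) abort("PLS could not extract any component (X has no variance).")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
  list(W = W, P = P, Q = Q, T = Tm, x_mean = x_mean, y_mean = y_mean,
       n_lv = a)
}

pls_coefficients <- function(core, nlv = core$n_lv) {
  nlv <- min(nlv, core$n_lv)
  W <- core$W[, seq_len(nlv), drop = FALSE]
  P <- core$P[, seq_len(nlv), drop = FALSE]
  Q <- core$Q[, seq_len(nlv), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))              # p x m
}

pls_predict_core <- function(core, X_new, nlv = core$n_lv) {
  B <- pls_coefficients(core, nlv)
  sweep(sweep(as.matrix(X_new), 2, core$x_mean) %*% B, 2, core$y_mean, "+")
}

# Venetian-blind (interleaved) fold assignment over the current row order.
venetian_folds <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L

max_usable_lv <- function(n, p, cv_folds, max_lv) {
  train_min <- n - ceiling(n / cv_folds)
  max(1L, min(max_lv, p, train_min - 1L))
}

#' Fit a PLS1 regression with cross-validated latent-variable count
#'
#' Fits NIPALS partial least squares on column-centered predictors and
#' response. The latent-variable (LV) count is chosen by venetian-blind
#' k-fold cross-validation: for each candidate count `1..max_lv` the root
#' mean square error of cross-validation (RMSECV) is computed, and the
#' smallest count attaining the minimum wins. The final model is refit on all
#' calibration rows.
#'
#' @param X numeric calibration matrix (n x p), or a `spectra_ds`.
#' @param y numeric response (length n), or (for a `spectra_ds`) the name of
#'   the response column, `"ssc"` or `"k"`.
#' @param max_lv maximum LV count considered (capped by the data size).
#' @param cv_folds number of cross-validation folds (>= 2).
#' @return A `pls_model` object with weights `W`, loadings `P`, y-loadings
#'   `Q`, coefficient vector `b`, centering offsets, the chosen `n_lv` and
#'   the `rmsecv` curve.
#' @export
fit_pls <- function(X, y, max_lv = 15, cv_folds = 10) {
  if (is_spectra_dataset(X)) {
    stopifnot(is.character(y), y %in% c("ssc", "k"))
    ds <- X; X <- spectra_matrix(ds); y <- ds[[y]]
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) abort("`y` length must equal nrow(X).")
  if (sd(y) < 1e-12) abort("Degenerate response: `y` has zero variance.")
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.")
  A <- max_usable_lv(n, ncol(X), cv_folds, max_lv)
  folds <- venetian_folds(n, cv_folds)
  press <- rep(0, A); counted <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    core <- nipals_pls_core(X[tr, , drop = FALSE], y[tr], A)
    for (a in seq_len(A)) {
      yh <- pls_predict_core(core, X[te, , drop = FALSE],
                             nlv = min(a, core$n_lv))[, 1]
      press[a] <- press[a] + sum((y[te] - yh)^2)
    }
  }
  rmsecv <- sqrt(press / n)
  n_lv <- which.min(rmsecv)                        # ties -> smallest lv
  core <- nipals_pls_core(X, y, n_lv)
  b <- pls_coefficients(core)[, 1]
  structure(list(
    W = core$W, P = core$P, q = core$Q[1, ], b = b,
    x_mean = core$x_mean, y_mean = core$y_mean,
    n_lv = core$n_lv, rmsecv = rmsecv, cv_folds = cv_folds
  ), class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param model a `pls_model`.
#' @param X_new matrix (m x p) or `spectra_ds` on the same bands.
#' @return Numeric vector of predictions.
#' @export
predict_pls <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  if (is_spectra_dataset(X_new)) X_new <- spectra_matrix(X_new)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$b)) {
    abort(sprintf("Band mismatch: model expects %d bands, got %d.",
                  length(model$b), ncol(X_new)))
  }
  drop(sweep(X_new, 2, model$x_mean) %*% model$b + model$y_mean)
}

#' @export
predict.pls_model <- function(object, newdata, ...) predict_pls(object, newdata)

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("# PLS regression: %d bands, %d latent variable(s)\n",
              length(x$b), x$n_lv))
  cat(sprintf("# RMSECV at chosen LV: %.5g\n", x$rmsecv[x$n_lv]))
  invisible(x)
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble(term = names(x$b) %||% paste0("band", seq_along(x$b)),
         estimate = unname(x$b))
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble(n_lv = x$n_lv, rmsecv = x$rmsecv[x$n_lv],
         max_lv_considered = length(x$rmsecv))
}

# PLS-DA --------------------------------------------------------------------

one_hot <- function(labels) {
  f <- factor(labels)
  Y <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  list(Y = Y, levels = levels(f))
}

plsda_decide <- function(scores, levels) {
  # argmax per row; exact ties resolved to the lower class index
  idx <- apply(scores, 1, function(r) which(r == max(r))[1])
  levels[idx]
}

#' Fit a PLS-DA classifier with cross-validated latent-variable count
#'
#' Encodes class labels one-hot, fits a PLS2 model, and classifies new
#' samples by the argmax of the continuous class predictions (exact ties go
#' to the lower class index). The LV count is chosen by venetian-blind k-fold
#' cross-validation, by default maximizing CV accuracy (ties to the smallest
#' count); `criterion = "rmsecv"` minimizes the root mean square error of the
#' one-hot predictions instead.
#'
#' @param X matrix or `spectra_ds`.
#' @param labels class labels (length n, >= 2 classes), or (for a
#'   `spectra_ds`) omitted to use `origin_class`.
#' @param max_lv,cv_folds as in [fit_pls()].
#' @param criterion `"accuracy"` or `"rmsecv"`.
#' @return A `plsda_model`.
#' @export
fit_plsda <- function(X, labels = NULL, max_lv = 15, cv_folds = 10,
                      criterion = c("accuracy", "rmsecv")) {
  criterion <- match.arg(criterion)
  if (is_spectra_dataset(X)) {
    labels <- labels %||% X$origin_class
    X <- spectra_matrix(X)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  enc <- one_hot(labels)
  if (length(enc$levels) < 2) abort("PLS-DA needs at least 2 classes.")
  tab <- table(labels)
  if (any(tab < cv_folds)) {
    warn("Some classes have fewer members than cv_folds.")
  }
  A <- max_usable_lv(n, ncol(X), cv_folds, max_lv)
  folds <- venetian_folds(n, cv_folds)
  correct <- rep(0, A); press <- rep(0, A)
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    core <- nipals_pls_core(X[tr, , drop = FALSE],
                            enc$Y[tr, , drop = FALSE], A)
    for (a in seq_len(A)) {
      sc <- pls_predict_core(core, X[te, , drop = FALSE],
                             nlv = min(a, core$n_lv))
      pred <- plsda_decide(sc, enc$levels)
      correct[a] <- correct[a] + sum(pred == as.character(labels)[te])
      press[a] <- press[a] + sum((enc$Y[te, , drop = FALSE] - sc)^2)
    }
  }
  cv_accuracy <- 100 * correct / n
  rmsecv <- sqrt(press / (n * ncol(enc$Y)))
  n_lv <- if (criterion == "accuracy") which.max(cv_accuracy)
          else which.min(rmsecv)
  core <- nipals_pls_core(X, enc$Y, n_lv)
  structure(list(
    core = core, B = pls_coefficients(core), levels = enc$levels,
    n_lv = core$n_lv, cv_accuracy = cv_accuracy, rmsecv = rmsecv,
    criterion = criterion
  ), class = "plsda_model")
}

#' Predict classes from a fitted PLS-DA model
#'
#' @param model a `plsda_model`.
#' @param X_new matrix or `spectra_ds`.
#' @param type `"class"` (default) or `"scores"` for the continuous class
#'   predictions.
#' @return Character vector of labels, or a score matrix.
#' @export
predict_plsda <- function(model, X_new, type = c("class", "scores")) {
  stopifnot(inherits(model, "plsda_model"))
  type <- match.arg(type)
  if (is_spectra_dataset(X_new)) X_new <- spectra_matrix(X_new)
  sc <- pls_predict_core(model$core, as.matrix(X_new))
  colnames(sc) <- model$levels
  if (type == "scores") return(sc)
  plsda_decide(sc, model$levels)
}

#' @export
glance.plsda_model <- function(x, ...) {
  tibble(n_lv = x$n_lv, cv_accuracy = x$cv_accuracy[x$n_lv],
         criterion = x$criterion)
}

# Random forest --------------------------------------------------------------

#' Random-forest classifier for origin discrimination
#'
#' Thin seeded wrapper around [randomForest::randomForest()]: a
#' bootstrap-aggregated tree ensemble with random feature subsampling
#' (`floor(sqrt(p))` features per split by default) and majority voting.
#'
#' @param X matrix or `spectra_ds`.
#' @param labels class labels (>= 2 classes), or omitted for a `spectra_ds`.
#' @param n_trees ensemble size.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param seed integer seed making training reproducible.
#' @return An `rft_model`.
#' @export
fit_rft <- function(X, labels = NULL, n_trees = 500, mtry = NULL, seed = 1L) {
  if (is_spectra_dataset(X)) {
    labels <- labels %||% X$origin_class
    X <- spectra_matrix(X)
  }
  X <- as.matrix(X)
  f <- factor(labels)
  if (nlevels(f) < 2) abort("Random forest needs at least 2 classes.")
  mtry <- mtry %||% max(1, floor(sqrt(ncol(X))))
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = f, ntree = n_trees,
                                    mtry = mtry)
  structure(list(fit = fit, levels = levels(f), seed = seed),
            class = "rft_model")
}

#' @rdname fit_rft
#' @param model an `rft_model`.
#' @param X_new matrix or `spectra_ds`.
#' @export
predict_rft <- function(model, X_new) {
  stopifnot(inherits(model, "rft_model"))
  if (is_spectra_dataset(X_new)) X_new <- spectra_matrix(X_new)
  as.character(predict(model$fit, as.matrix(X_new)))
}
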