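# Independent oracles, written with explicit loops and kept deliberately
# separate from the package's vectorized implementations.

# Textbook NIPALS PLS1: one component at a time, explicit deflation.
oracle_nipals_pls1 <- function(X, y, nlv) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- X
  for (j in seq_len(ncol(X))) E[, j] <- X[, j] - x_mean[j]
  f <- y - y_mean
  p <- ncol(X)
  W <- matrix(0, p, nlv); P <- matrix(0, p, nlv); q <- numeric(nlv)
  for (a in seq_len(nlv)) {
    w <- numeric(p)
    for (j in seq_len(p)) w[j] <- sum(E[, j] * f)
    w <- w / sqrt(sum(w^2))
    tt <- numeric(nrow(E))
    for (i in seq_len(nrow(E))) tt[i] <- sum(E[i, ] * w)
    pp <- numeric(p)
    for (j in seq_len(p)) pp[j] <- sum(E[, j] * tt) / sum(tt^2)
    qa <- sum(f * tt) / sum(tt^2)
    for (j in seq_len(p)) E[, j] <- E[, j] - tt * pp[j]
    f <- f - qa * tt
    W[, a] <- w; P[, a] <- pp; q[a] <- qa
  }
  b <- W %*% solve(t(P) %*% W) %*% q
  list(b = drop(b), x_mean = x_mean, y_mean = y_mean)
}

# Greedy SPXY / Kennard-Stone on the joint normalized distance, explicit
# loops over candidates.
oracle_spxy <- function(X, y, n_cal) {
  n <- nrow(X)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  d <- dx / max(dx) + dy / max(dy)
  best <- c(1, 2); best_d <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > best_d) { best_d <- d[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand_best <- NA; cand_d <- -Inf
    for (i in seq_len(n)) {
      if (i %in% sel) next
      mind <- Inf
      for (s in sel) if (d[i, s] < mind) mind <- d[i, s]
      if (mind > cand_d) { cand_d <- mind; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# Local least-squares polynomial fit evaluated at the window centre:
# the defining property of the Savitzky-Golay filter.
oracle_sg_point <- function(window_vals, polyorder, deriv = 0) {
  m <- length(window_vals)
  half <- (m - 1) / 2
  z <- seq(-half, half)
  V <- outer(z, 0:polyorder, "^")
  beta <- solve(t(V) %*% V, t(V) %*% window_vals)
  factorial(deriv) * beta[deriv + 1]
}

# Explicit de-interleave of a flat ENVI vector (sample fastest).
oracle_deinterleave <- function(vals, rows, cols, bands, interleave) {
  arr <- array(0, dim = c(rows, cols, bands))
  idx <- 1
  if (interleave == "bsq") {
    for (b in seq_len(bands)) for (r in seq_len(rows)) for (cc in seq_len(cols)) {
      arr[r, cc, b] <- vals[idx]; idx <- idx + 1
    }
  } else if (interleave == "bil") {
    for (r in seq_len(rows)) for (b in seq_len(bands)) for (cc in seq_len(cols)) {
      arr[r, cc, b] <- vals[idx]; idx <- idx + 1
    }
  } else {
    for (r in seq_len(rows)) for (cc in seq_len(cols)) for (b in seq_len(bands)) {
      arr[r, cc, b] <- vals[idx]; idx <- idx + 1
    }
  }
  arr
}

# Minimum-norm least squares via the pseudoinverse.
oracle_minnorm_ls <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  sv <- svd(Xc)
  pos <- sv$d > 1e-10 * sv$d[1]
  b <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% yc) / sv$d[pos])
  drop(b)
}
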