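#' PLS1 regression (NIPALS)
#'
#' Partial least squares regression of a single response on centered data,
#' computed by NIPALS-style deflation. This is the regression core of the
#' CARS wavelength selector (band weights are the absolute regression
#' coefficients) and of the RMSECV diagnostics.
#'
#' @param X numeric matrix (n x p) or [spectra_matrix()].
#' @param y numeric response, length n.
#' @param n_components number of latent components; must not exceed the rank
#'   of the centered predictor matrix.
#' @return Object of class `pls_model`: `coefficients` (length p, on the
#'   original scale), `x_means`, `y_mean`, `n_components`, and the weight /
#'   loading matrices.
#' @examples
#' X <- matrix(rnorm(60), 20)
#' m <- pls_fit(X, X %*% c(1, -1, 0.5) + rnorm(20, sd = .1), 2)
#' predict(m, X)[1:3]
#' @export
pls_fit <- function(X, y, n_components) {
  if (inherits(X, "spectra_matrix")) X <- X$X
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_bad("nrow(X) != length(y)")
  if (nrow(X) < 3L) stop_bad("PLS needs at least 3 samples")
  if (any(!is.finite(y))) stop_bad("y must be finite")
  n_components <- as.integer(n_components)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_means)
  yc <- y - y_mean
  rank <- qr(Xc)$rank
  if (n_components > rank) {
    stop_bad("n_components (", n_components, ") exceeds predictor rank (", rank, ")")
  }
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # response fully explained (or orthogonal): keep zero component
      W[, a] <- 0; P[, a] <- 0; q[a] <- 0
      next
    }
    w <- w / nw
    t_score <- Xd %*% w
    tt <- sum(t_score^2)
    p_load <- crossprod(Xd, t_score) / tt
    q_a <- sum(yd * t_score) / tt
    Xd <- Xd - t_score %*% t(p_load)
    yd <- yd - t_score * q_a
    W[, a] <- w; P[, a] <- p_load; q[a] <- q_a
  }
  # b = W (P'W)^-1 q, guarded for zero components
  keep <- which(colSums(abs(W)) > 0)
  coefs <- if (length(keep)) {
    Wk <- W[, keep, drop = FALSE]; Pk <- P[, keep, drop = FALSE]
    drop(Wk %*% solve(crossprod(Pk, Wk), q[keep]))
  } else {
    numeric(p)
  }
  structure(
    list(coefficients = coefs, x_means = x_means, y_mean = y_mean,
         n_components = n_components, W = W, P = P, q = q),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d component(s), %d band(s)>\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' @export
coef.pls_model <- function(object, ...) object$coefficients

#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  drop(sweep(newdata, 2, object$x_means) %*% object$coefficients) + object$y_mean
}

# Safe component count for internal fits.
pls_ncomp <- function(n, p, cap = 10L) {
  max(1L, min(cap, p, n - 2L))
}

# Fit PLS with the largest feasible n_components <= cap (backing off if the
# requested count exceeds the realized rank).
pls_fit_safe <- function(X, y, cap = 10L) {
  nc <- pls_ncomp(nrow(X), ncol(X), cap)
  repeat {
    m <- tryCatch(pls_fit(X, y, nc), error = function(e) NULL)
    if (!is.null(m) || nc == 1L) return(m)
    nc <- nc - 1L
  }
}

# k-fold RMSE of cross-validated PLS predictions; folds are a list of index
# vectors (so every caller controls the fold randomness).
pls_rmsecv <- function(X, y, folds, cap = 10L) {
  X <- as.matrix(X)
  err2 <- 0
  for (fold in folds) {
    m <- pls_fit_safe(X[-fold, , drop = FALSE], y[-fold], cap)
    if (is.null(m)) return(Inf)
    err2 <- err2 + sum((y[fold] - predict(m, X[fold, , drop = FALSE]))^2)
  }
  sqrt(err2 / length(y))
}

# Random k-fold partition of n indices.
make_folds <- function(n, k) {
  split(sample_int(n, n), rep_len(seq_len(k), n))
}
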