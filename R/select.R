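#' Selection result container
#'
#' @description Internal constructor for the result of a wavelength-selection
#' method (PCA, SPA, CARS). Fields: `method`, `selected_band_indices`
#' (sorted, unique; empty for the PCA-scores path), `projected_features`
#' (PCA scores, else `NULL`), and method-specific `diagnostics`.
#' @keywords internal
selection_result <- function(method, selected_band_indices = integer(0),
                             projected_features = NULL, projected_test = NULL,
                             diagnostics = list()) {
  idx <- sort(unique(as.integer(selected_band_indices)))
  structure(
    list(method = method, selected_band_indices = idx,
         projected_features = projected_features,
         projected_test = projected_test,
         diagnostics = diagnostics),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s, %s>\n", x$method,
              if (length(x$selected_band_indices)) {
                paste(length(x$selected_band_indices), "band(s) selected")
              } else {
                paste0(ncol(x$projected_features %||% matrix(0, 0, 0)),
                       " component score(s)")
              }))
  invisible(x)
}

#' Plot selector diagnostics
#'
#' For SPA, the minimum cross-validated RMSE against the number of selected
#' wavelengths; for CARS, the retained-band schedule and the RMSECV per
#' sampling run; for PCA, the cumulative contribution of the leading
#' components.
#'
#' @param x a `selection_result`.
#' @param ... passed to the underlying plot call.
#' @export
plot.selection_result <- function(x, ...) {
  d <- x$diagnostics
  if (x$method == "spa") {
    graphics::plot(d$m_values, d$rmse_curve, type = "b", xlab = "number of wavelengths",
                   ylab = "cross-validated RMSE", main = "SPA", ...)
    graphics::abline(v = d$best_m, lty = 2)
  } else if (x$method == "cars") {
    old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    graphics::plot(d$retained_counts, type = "l", xlab = "sampling run",
                   ylab = "retained bands", main = "CARS", ...)
    graphics::plot(d$rmsecv_curve, type = "l", xlab = "sampling run",
                   ylab = "RMSECV")
    graphics::abline(v = d$winning_run, lty = 2)
  } else {
    graphics::plot(seq_along(d$cumulative_top20), d$cumulative_top20, type = "b",
                   xlab = "principal component", ylab = "cumulative contribution (%)",
                   main = "PCA", ...)
  }
  invisible(x)
}

#' Principal-component reduction
#'
#' Centers on the training columns, extracts the leading principal components
#' and returns the train/test score matrices as the reduced feature set (the
#' "new coordinate system"). Per-component contribution rates (eigenvalue
#' shares, percent, summing to 100 over all components) and the cumulative
#' contribution of the top 20 are reported as diagnostics, together with the
#' loadings for wavelength inspection.
#'
#' @param train,test [spectra_matrix()] or plain matrices; `test` optional.
#' @param n_components number of scores to keep (default 3).
#' @return A `selection_result` with `projected_features` (train scores),
#'   `projected_test`, and diagnostics `contribution_pct`,
#'   `cumulative_top20`, `loadings`.
#' @export
pca_reduce <- function(train, test = NULL, n_components = 3L) {
  Xtr <- if (inherits(train, "spectra_matrix")) train$X else as.matrix(train)
  n_components <- as.integer(n_components)
  mu <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * max(sv$d))
  if (n_components > rank) {
    stop_bad("n_components (", n_components, ") exceeds data rank (", rank, ")")
  }
  contrib <- 100 * ev / sum(ev)
  scores <- Xc %*% sv$v[, seq_len(n_components), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_components))
  test_scores <- NULL
  if (!is.null(test)) {
    Xte <- if (inherits(test, "spectra_matrix")) test$X else as.matrix(test)
    test_scores <- sweep(Xte, 2, mu) %*% sv$v[, seq_len(n_components), drop = FALSE]
    colnames(test_scores) <- colnames(scores)
  }
  selection_result(
    "pca",
    projected_features = scores,
    projected_test = test_scores,
    diagnostics = list(
      contribution_pct = contrib,
      cumulative_top20 = cumsum(contrib)[seq_len(min(20L, length(contrib)))],
      loadings = sv$v[, seq_len(n_components), drop = FALSE],
      center = mu
    )
  )
}

#' Successive projections algorithm (SPA)
#'
#' Forward wavelength selection that grows minimally collinear band chains:
#' starting from every band in turn, the next band is always the one whose
#' column has the largest residual norm after projecting out the span of the
#' chain built so far. Every chain prefix with `m_min`..`m_max` bands is then
#' scored by the cross-validated RMSE of a multiple linear regression on `y`,
#' and the chain with the smallest RMSE wins.
#'
#' @param train [spectra_matrix()] or matrix of training spectra.
#' @param y numeric response (here: the grade code 1-4).
#' @param m_min,m_max candidate chain lengths (default 5-30; `m_max` must be
#'   below the band count).
#' @param cv_folds folds for the RMSE evaluation (default 5).
#' @param seed integer seed for the fold assignment.
#' @return A `selection_result`; diagnostics hold the per-m minimum RMSE
#'   curve (`m_values`, `rmse_curve`), the winning `best_m`, `best_start`
#'   and `best_rmse`.
#' @export
spa_select <- function(train, y, m_min = 5L, m_max = 30L, cv_folds = 5L,
                       seed = 1L) {
  X <- if (inherits(train, "spectra_matrix")) train$X else as.matrix(train)
  y <- as.numeric(y)
  p <- ncol(X); n <- nrow(X)
  m_min <- as.integer(m_min); m_max <- as.integer(m_max)
  if (m_max >= p) stop_bad("m_max must be smaller than the number of bands")
  if (m_min < 1L || m_min > m_max) stop_bad("need 1 <= m_min <= m_max")
  with_seed(seed, {
    folds <- make_folds(n, cv_folds)
    best <- list(rmse = Inf, chain = NULL, start = NA_integer_, m = NA_integer_)
    rmse_by_m <- rep(Inf, m_max - m_min + 1L)
    m_values <- m_min:m_max
    for (start in seq_len(p)) {
      chain <- spa_chain(X, start, m_max)
      for (mi in seq_along(m_values)) {
        m <- m_values[mi]
        if (length(chain) < m) break
        sel <- chain[seq_len(m)]
        rmse <- mlr_rmsecv(X[, sel, drop = FALSE], y, folds)
        if (rmse < rmse_by_m[mi]) rmse_by_m[mi] <- rmse
        if (rmse < best$rmse) {
          best <- list(rmse = rmse, chain = sel, start = start, m = m)
        }
      }
    }
    selection_result(
      "spa", selected_band_indices = best$chain,
      diagnostics = list(m_values = m_values, rmse_curve = rmse_by_m,
                         best_m = best$m, best_start = best$start,
                         best_rmse = best$rmse)
    )
  })
}

# Build one successive-projection chain of (up to) m bands from a start band.
# Degenerate (numerically collinear) candidates truncate the chain early.
spa_chain <- function(X, start, m) {
  p <- ncol(X)
  R <- X                      # residual columns after projecting out the chain
  chain <- integer(0)
  current <- start
  tol <- max(abs(X)) * 1e-10 + 1e-12
  for (step in seq_len(m)) {
    chain <- c(chain, current)
    if (step == m) break
    u <- R[, current]
    uu <- sum(u^2)
    if (uu < tol^2) break
    R <- R - u %*% (crossprod(u, R) / uu)
    norms <- sqrt(colSums(R^2))
    norms[chain] <- -Inf
    nxt <- as.integer(which.max(norms))
    if (norms[nxt] < tol) break
    current <- nxt
  }
  as.integer(unname(chain))
}

# Cross-validated RMSE of an ordinary multiple linear regression.
mlr_rmsecv <- function(X, y, folds) {
  err2 <- 0
  for (fold in folds) {
    Xtr <- cbind(1, X[-fold, , drop = FALSE])
    fit <- stats::lm.fit(Xtr, y[-fold])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, X[fold, , drop = FALSE]) %*% cf)
    err2 <- err2 + sum((y[fold] - pred)^2)
  }
  sqrt(err2 / length(y))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength selection in the "survival of the fittest" spirit.
#' In sampling run i of N: (1) a Monte-Carlo subset of the training samples
#' is drawn; (2) a PLS model is fitted on the currently retained bands and
#' each band is weighted by its normalized absolute regression coefficient;
#' (3) an exponentially decreasing schedule
#' \eqn{r_i = a e^{-k i}}, with \eqn{a = (p/2)^{1/(N-1)}} and
#' \eqn{k = \ln(p/2)/(N-1)}, enforces retention of the top
#' \eqn{round(r_i p)} bands — all p bands in run 1 and exactly 2 in run N;
#' (4) adaptive reweighted sampling redraws the retained set with
#' probability proportional to the weights (survivors topped back up to the
#' scheduled count by weight, so the realized counts follow the schedule
#' exactly); (5) the cross-validated RMSECV of a PLS model on the survivors
#' is recorded. The run with the minimum RMSECV wins and its band set is
#' returned.
#'
#' @param train [spectra_matrix()] or matrix of training spectra.
#' @param y numeric response (here: the grade code 1-4).
#' @param n_runs Monte-Carlo sampling runs N (default 100).
#' @param cv_folds folds for the RMSECV (default 5).
#' @param mc_fraction fraction of training samples drawn per run (default 0.8).
#' @param seed integer seed.
#' @param ncomp_cap maximum PLS components for the internal fits (default 10).
#' @return A `selection_result`; diagnostics hold `retained_counts`,
#'   `rmsecv_curve` and `winning_run`.
#' @export
cars_select <- function(train, y, n_runs = 100L, cv_folds = 5L,
                        mc_fraction = 0.8, seed = 1L, ncomp_cap = 10L) {
  X <- if (inherits(train, "spectra_matrix")) train$X else as.matrix(train)
  y <- as.numeric(y)
  p <- ncol(X); n <- nrow(X)
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop_bad("n_runs must be >= 2")
  if (p < 3L) stop_bad("CARS needs at least 3 bands")
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  sched <- pmax(2L, pmin(p, as.integer(round(p * a * exp(-k * seq_len(n_runs))))))
  n_mc <- max(3L, round(mc_fraction * n))
  with_seed(seed, {
    folds <- make_folds(n, cv_folds)
    retained <- seq_len(p)
    retained_counts <- integer(n_runs)
    rmsecv <- rep(NA_real_, n_runs)
    sets <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      if (length(retained) < 2L) {
        retained_counts <- retained_counts[seq_len(i - 1L)]
        rmsecv <- rmsecv[seq_len(i - 1L)]
        sets <- sets[seq_len(i - 1L)]
        break
      }
      rows <- sample_int(n, n_mc)
      m <- pls_fit_safe(X[rows, retained, drop = FALSE], y[rows], ncomp_cap)
      w <- if (is.null(m)) rep(1, length(retained)) else abs(m$coefficients)
      if (sum(w) == 0) w <- rep(1, length(retained))
      w <- w / sum(w)
      keep_n <- min(sched[i], length(retained))
      ord <- order(w, decreasing = TRUE)
      retained <- retained[ord]; w <- w[ord]
      retained <- retained[seq_len(keep_n)]; w <- w[seq_len(keep_n)]
      # adaptive reweighted sampling; survivors topped up to the schedule
      drawn <- unique(sample_int(keep_n, keep_n, replace = TRUE, prob = w))
      if (length(drawn) < keep_n) {
        drawn <- c(drawn, setdiff(seq_len(keep_n), drawn)[
          seq_len(keep_n - length(drawn))])
      }
      retained <- sort(retained[drawn])
      retained_counts[i] <- length(retained)
      rmsecv[i] <- pls_rmsecv(X[, retained, drop = FALSE], y, folds, ncomp_cap)
      sets[[i]] <- retained
    }
    win <- which.min(rmsecv)
    selection_result(
      "cars", selected_band_indices = sets[[win]],
      diagnostics = list(retained_counts = retained_counts,
                         rmsecv_curve = rmsecv, winning_run = win,
                         schedule = sched[seq_along(retained_counts)])
    )
  })
}
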