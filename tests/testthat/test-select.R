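# ---- PCA -------------------------------------------------------------------

test_that("PCA contributions sum to 100 and rank-1 data loads PC1 fully", {
  set.seed(1)
  X <- matrix(rnorm(50), 10, 5)
  res <- pca_reduce(X, n_components = 3)
  expect_equal(sum(res$diagnostics$contribution_pct), 100, tolerance = 1e-8)

  line <- outer(rnorm(10), c(1, 2, 3, 4))  # exactly rank 1 after centering? no: add centroid
  line <- sweep(line, 2, c(5, 5, 5, 5), `+`)
  res1 <- pca_reduce(line, n_components = 1)
  expect_equal(res1$diagnostics$contribution_pct[1], 100, tolerance = 1e-8)
  expect_error(pca_reduce(line, n_components = 2), "rank")
})

test_that("PCA scores match a covariance-eigendecomposition oracle up to sign", {
  set.seed(2)
  for (i in 1:20) {
    X <- matrix(rnorm(20), 5, 4)
    res <- pca_reduce(X, n_components = 3)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    ei <- eigen(cov(Xc))
    oracle <- Xc %*% ei$vectors[, 1:3]
    for (j in 1:3) {
      agree <- min(max(abs(res$projected_features[, j] - oracle[, j])),
                   max(abs(res$projected_features[, j] + oracle[, j])))
      expect_lt(agree, 1e-8)
    }
    # eigenvalue shares must match too
    expect_equal(res$diagnostics$contribution_pct[1:3],
                 100 * ei$values[1:3] / sum(ei$values), tolerance = 1e-8)
  }
})

test_that("PCA projects the test set with training statistics", {
  set.seed(3)
  tr <- matrix(rnorm(40), 10, 4)
  te <- matrix(rnorm(20), 5, 4)
  res <- pca_reduce(tr, te, n_components = 2)
  oracle <- sweep(te, 2, colMeans(tr)) %*% res$diagnostics$loadings[, 1:2]
  expect_equal(unname(res$projected_test), unname(oracle), tolerance = 1e-10)
})

# ---- SPA -------------------------------------------------------------------

test_that("successive projection picks the orthogonal complement, never duplicates", {
  b1 <- c(1, 0, 0, 0); b2 <- c(0, 1, 0, 0); b3 <- b1 + b2
  X <- cbind(b1, b2, b3)
  chain <- ovospec:::spa_chain(X, start = 1, m = 2)
  expect_equal(chain, c(1, 2))
  # a duplicated band has zero residual and is never chained with its twin
  Xd <- cbind(b1, b1, rnorm(4))
  chain_d <- ovospec:::spa_chain(Xd, start = 1, m = 3)
  expect_false(all(c(1, 2) %in% chain_d))
})

test_that("SPA equals the brute-force minimum over all start-band chains", {
  spa_oracle <- function(X, y, m_min, m_max, folds) {
    # independent implementation: qr-based projections + per-fold lm()
    eval_chain <- function(sel) {
      err2 <- 0
      for (fold in folds) {
        d_tr <- data.frame(y = y[-fold], X[-fold, sel, drop = FALSE])
        d_te <- data.frame(X[fold, sel, drop = FALSE])
        names(d_tr)[-1] <- names(d_te) <- paste0("v", seq_along(sel))
        fit <- lm(y ~ ., data = d_tr)
        err2 <- err2 + sum((y[fold] - predict(fit, d_te))^2)
      }
      sqrt(err2 / length(y))
    }
    build <- function(start, m) {
      chain <- start
      while (length(chain) < m) {
        Q <- qr.Q(qr(X[, chain, drop = FALSE]))
        resid <- X - Q %*% (t(Q) %*% X)
        norms <- sqrt(colSums(resid^2))
        norms[chain] <- -Inf
        if (max(norms) < 1e-8) break
        chain <- c(chain, which.max(norms))
      }
      chain
    }
    best <- list(rmse = Inf, chain = NULL)
    for (start in seq_len(ncol(X))) {
      full <- build(start, m_max)
      for (m in m_min:min(m_max, length(full))) {
        r <- eval_chain(full[seq_len(m)])
        if (r < best$rmse) best <- list(rmse = r, chain = sort(full[seq_len(m)]))
      }
    }
    best
  }
  set.seed(4)
  for (i in 1:20) {
    n <- 16; p <- sample(5:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    seed <- 100 + i
    res <- spa_select(X, y, m_min = 2, m_max = 3, cv_folds = 4, seed = seed)
    folds <- ovospec:::with_seed(seed, ovospec:::make_folds(n, 4))
    oracle <- spa_oracle(X, y, 2, 3, folds)
    expect_equal(res$selected_band_indices, oracle$chain)
    expect_equal(res$diagnostics$best_rmse, oracle$rmse, tolerance = 1e-10)
  }
})

test_that("SPA validates its chain-length window", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(spa_select(X, rnorm(10), m_min = 2, m_max = 4), "smaller")
  expect_error(spa_select(X, rnorm(10), m_min = 3, m_max = 2), "m_min")
})

# ---- CARS ------------------------------------------------------------------

test_that("CARS retention schedule starts at p and ends at exactly 2 bands", {
  set.seed(5)
  X <- matrix(rnorm(40 * 100), 40, 100)
  y <- rnorm(40)
  res <- cars_select(X, y, n_runs = 100, cv_folds = 4, seed = 6)
  rc <- res$diagnostics$retained_counts
  expect_equal(rc[1], 100L)
  expect_equal(rc[100], 2L)
  expect_true(all(diff(rc) <= 0))
})

test_that("CARS is deterministic given a seed", {
  set.seed(7)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- X[, 3] + rnorm(30, sd = 0.2)
  a <- cars_select(X, y, n_runs = 20, seed = 8)
  b <- cars_select(X, y, n_runs = 20, seed = 8)
  expect_identical(a, b)
})

test_that("CARS concentrates on planted informative bands (quick check)", {
  set.seed(9)
  n <- 100; p <- 40
  planted <- c(4, 11, 23, 37)
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, planted] %*% c(2, -2, 1.5, 1) + rnorm(n, sd = 0.3)
  res <- cars_select(X, drop(y), n_runs = 50, seed = 10)
  expect_gte(sum(planted %in% res$selected_band_indices), 3)
  # winning subset beats the full-band RMSECV
  folds <- ovospec:::with_seed(10, ovospec:::make_folds(n, 5))
  full <- ovospec:::pls_rmsecv(X, drop(y), folds)
  win <- res$diagnostics$rmsecv_curve[res$diagnostics$winning_run]
  expect_lte(win, full)
})

test_that("selected indices are unique, sorted and in range for all selectors", {
  set.seed(11)
  X <- matrix(rnorm(60 * 25), 60, 25)
  y <- as.numeric(rep(1:4, 15))
  for (res in list(spa_select(X, y, m_min = 2, m_max = 5, seed = 1),
                   cars_select(X, y, n_runs = 15, seed = 1))) {
    idx <- res$selected_band_indices
    expect_true(!is.unsorted(idx))
    expect_equal(anyDuplicated(idx), 0L)
    expect_true(all(idx >= 1 & idx <= 25))
    expect_lte(length(idx), 30)
  }
})
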