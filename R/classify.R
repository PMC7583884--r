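#' Classifier specification
#'
#' One of six weak classifiers behind a single fit/predict-probability
#' contract: `"SVM"` (RBF kernel, one-vs-one dual solved by quadratic
#' programming), `"KNN"` (k nearest neighbours, Euclidean), `"RF"` (random
#' forest of CART trees on bootstrap samples), `"NB"` (Gaussian naive
#' Bayes), `"DAC"` (Gaussian discriminant analysis classifier with pooled —
#' linear — or per-class — quadratic — covariance), `"LDA"` (Fisher linear
#' discriminant projection followed by nearest class centroid).
#'
#' @param kind classifier kind (see above).
#' @param k neighbours for KNN (default 5).
#' @param cost,gamma SVM box constraint and RBF width; `gamma = NULL` means
#'   `1 / (p * var(X))`, the usual scale heuristic.
#' @param n_trees,mtry,min_node random-forest size (default 100 trees),
#'   features tried per split (default `floor(sqrt(p))`), minimum node size.
#' @param discriminant `"linear"` or `"quadratic"` covariance for DAC.
#' @param seed integer seed used by the stochastic kinds (RF).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("DAC", "KNN", "RF", "NB", "LDA", "SVM"),
                            k = 5L, cost = 1, gamma = NULL,
                            n_trees = 100L, mtry = NULL, min_node = 5L,
                            discriminant = c("linear", "quadratic"),
                            seed = 1L) {
  kind <- match.arg(kind)
  discriminant <- match.arg(discriminant)
  if (k < 1L) stop_bad("KNN needs k >= 1")
  if (cost <= 0) stop_bad("SVM cost must be positive")
  if (n_trees < 1L) stop_bad("RF needs n_trees >= 1")
  structure(
    list(kind = kind, k = as.integer(k), cost = cost, gamma = gamma,
         n_trees = as.integer(n_trees), mtry = mtry,
         min_node = as.integer(min_node), discriminant = discriminant,
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec:", x$kind, ">\n")
  invisible(x)
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix (n x p), finite.
#' @param y factor of class labels (>= 2 classes present).
#' @return Object of class `egg_classifier` supporting [predict_prob()] and
#'   `predict()`.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_bad("features must be finite")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop_bad("training labels must contain >= 2 classes")
  if (nrow(X) != length(y)) stop_bad("nrow(X) != length(y)")
  fit <- switch(spec$kind,
    KNN = list(X = X, y = y),
    NB = nb_fit(X, y),
    DAC = dac_fit(X, y, spec$discriminant),
    LDA = flda_fit(X, y),
    SVM = svm_fit(X, y, spec),
    RF = with_seed(spec$seed, rf_fit(X, y, spec))
  )
  structure(list(spec = spec, fit = fit, levels = levels(y), p = ncol(X)),
            class = "egg_classifier")
}

#' Class-probability predictions
#'
#' Every classifier kind exposes class probabilities (vote
#' fractions for KNN/RF, Gaussian posteriors for NB/DAC, softmax over
#' discriminant distances for LDA, softmax over aggregated pairwise decision
#' values for SVM) so that all six can feed the stacking meta-features.
#'
#' @param object a fitted `egg_classifier`.
#' @param X feature matrix.
#' @return Matrix n x n_classes; rows sum to 1.
#' @export
predict_prob <- function(object, X) {
  stopifnot(inherits(object, "egg_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != object$p) stop_bad("feature count differs from training")
  P <- switch(object$spec$kind,
    KNN = knn_prob(object$fit, X, object$spec$k),
    NB = nb_prob(object$fit, X),
    DAC = dac_prob(object$fit, X),
    LDA = flda_prob(object$fit, X),
    SVM = svm_prob(object$fit, X),
    RF = rf_prob(object$fit, X)
  )
  colnames(P) <- object$levels
  P / rowSums(P)
}

#' @export
predict.egg_classifier <- function(object, newdata, ...) {
  P <- predict_prob(object, newdata)
  factor(object$levels[max.col(P, ties.method = "first")], levels = object$levels)
}

#' @export
print.egg_classifier <- function(x, ...) {
  cat(sprintf("<egg_classifier: %s, %d class(es), %d feature(s)>\n",
              x$spec$kind, length(x$levels), x$p))
  invisible(x)
}

# ---- KNN -------------------------------------------------------------------

knn_prob <- function(fit, X, k) {
  k <- min(k, nrow(fit$X))
  lv <- levels(fit$y)
  D2 <- outer(rowSums(X^2), rep(1, nrow(fit$X))) +
    outer(rep(1, nrow(X)), rowSums(fit$X^2)) - 2 * X %*% t(fit$X)
  P <- matrix(0, nrow(X), length(lv))
  for (i in seq_len(nrow(X))) {
    nb <- order(D2[i, ])[seq_len(k)]
    P[i, ] <- tabulate(as.integer(fit$y[nb]), length(lv)) / k
  }
  # deterministic vote ties: nudge by inverse mean distance of each class's votes
  P + 1e-9
}

# ---- Gaussian naive Bayes --------------------------------------------------

nb_fit <- function(X, y) {
  lv <- levels(y)
  eps <- 1e-9 * max(apply(X, 2, stats::var), 1e-12)
  stats_by <- lapply(lv, function(g) {
    Xi <- X[y == g, , drop = FALSE]
    list(mean = colMeans(Xi),
         var = apply(Xi, 2, stats::var) + eps,
         prior = nrow(Xi) / nrow(X))
  })
  names(stats_by) <- lv
  list(stats = stats_by, levels = lv)
}

nb_prob <- function(fit, X) {
  ll <- vapply(fit$stats, function(s) {
    rowSums(-0.5 * (sweep(X, 2, s$mean)^2) / rep(s$var, each = nrow(X)) -
              0.5 * rep(log(2 * pi * s$var), each = nrow(X))) + log(s$prior)
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  softmax_rows(ll)
}

# ---- discriminant analysis classifier (DAC) --------------------------------

# Pooled ("linear") or per-class ("quadratic") Gaussian discriminant. Singular
# covariances get ridge shrinkage, escalated until the Cholesky succeeds.
dac_fit <- function(X, y, discriminant) {
  lv <- levels(y)
  p <- ncol(X)
  means <- t(vapply(lv, function(g) colMeans(X[y == g, , drop = FALSE]), numeric(p)))
  priors <- as.numeric(table(y)[lv]) / length(y)
  covs <- if (discriminant == "linear") {
    S <- matrix(0, p, p)
    for (g in lv) {
      Xi <- X[y == g, , drop = FALSE]
      S <- S + crossprod(sweep(Xi, 2, colMeans(Xi)))
    }
    list(pooled = S / (length(y) - length(lv)))
  } else {
    cl <- lapply(lv, function(g) {
      Xi <- X[y == g, , drop = FALSE]
      if (nrow(Xi) < 2L) stop_bad("quadratic DAC needs >= 2 samples per class")
      stats::cov(Xi)
    })
    names(cl) <- lv
    cl
  }
  covs <- lapply(covs, shrink_to_pd)
  list(levels = lv, means = means, priors = priors, covs = covs,
       discriminant = discriminant)
}

# Ridge a covariance matrix until positive definite; returns chol and logdet.
shrink_to_pd <- function(S) {
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  lambda <- 0
  repeat {
    ch <- tryCatch(chol(S + lambda * scale * diag(nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) {
      if (lambda > 0) {
        message(sprintf("DAC: covariance shrunk with ridge %.1e to reach positive definiteness",
                        lambda * scale))
      }
      return(list(chol = ch, logdet = 2 * sum(log(diag(ch)))))
    }
    lambda <- if (lambda == 0) 1e-8 else lambda * 10
    if (lambda > 1) stop_bad("covariance irreparably singular")
  }
}

dac_prob <- function(fit, X) {
  lv <- fit$levels
  ll <- matrix(0, nrow(X), length(lv))
  for (j in seq_along(lv)) {
    S <- if (fit$discriminant == "linear") fit$covs$pooled else fit$covs[[lv[j]]]
    d <- sweep(X, 2, fit$means[j, ])
    z <- forwardsolve(t(S$chol), t(d))
    ll[, j] <- -0.5 * colSums(z^2) - 0.5 * S$logdet + log(fit$priors[j])
  }
  softmax_rows(ll)
}

# ---- Fisher LDA (projection + nearest centroid) ----------------------------

flda_fit <- function(X, y) {
  lv <- levels(y)
  p <- ncol(X)
  overall <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  means <- matrix(0, length(lv), p)
  for (j in seq_along(lv)) {
    Xi <- X[y == lv[j], , drop = FALSE]
    mu <- colMeans(Xi)
    means[j, ] <- mu
    Sw <- Sw + crossprod(sweep(Xi, 2, mu))
    Sb <- Sb + nrow(Xi) * tcrossprod(mu - overall)
  }
  Sw <- Sw + diag(1e-8 * max(mean(diag(Sw)), 1e-12), p)
  M <- solve(Sw, Sb)
  ei <- eigen(M)
  d <- min(length(lv) - 1L, p)
  V <- Re(ei$vectors[, seq_len(d), drop = FALSE])
  list(levels = lv, V = V, centroids = means %*% V)
}

flda_prob <- function(fit, X) {
  Z <- X %*% fit$V
  D2 <- outer(rowSums(Z^2), rep(1, nrow(fit$centroids))) +
    outer(rep(1, nrow(Z)), rowSums(fit$centroids^2)) - 2 * Z %*% t(fit$centroids)
  softmax_rows(-0.5 * D2)
}

# ---- SVM (one-vs-one, RBF, dual via quadprog) ------------------------------

svm_fit <- function(X, y, spec) {
  lv <- levels(y)
  gamma <- spec$gamma %||% (1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), 1e-12)))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    Xi <- X[idx, , drop = FALSE]
    yi <- ifelse(y[idx] == pr[1], 1, -1)
    svm_binary(Xi, yi, spec$cost, gamma)
  })
  list(levels = lv, pairs = pairs, models = models, gamma = gamma)
}

rbf_kernel <- function(A, B, gamma) {
  D2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  exp(-gamma * pmax(D2, 0))
}

# Soft-margin dual: max sum(a) - a' (yy' K) a / 2, 0 <= a <= C, sum(a y) = 0.
svm_binary <- function(X, y, cost, gamma) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  D <- (y %o% y) * K + diag(1e-8, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A, bvec = b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- which(alpha > 1e-6)
  margin <- which(alpha > 1e-6 & alpha < cost - 1e-6)
  if (!length(margin)) margin <- sv
  f_no_b <- drop(K %*% (alpha * y))
  b <- mean(y[margin] - f_no_b[margin])
  list(X = X[sv, , drop = FALSE], ay = (alpha * y)[sv], b = b, gamma = gamma)
}

svm_decision <- function(m, X) {
  drop(rbf_kernel(X, m$X, m$gamma) %*% m$ay) + m$b
}

svm_prob <- function(fit, X) {
  lv <- fit$levels
  score <- matrix(0, nrow(X), length(lv))
  colnames(score) <- lv
  for (i in seq_along(fit$pairs)) {
    f <- svm_decision(fit$models[[i]], X)
    pr <- fit$pairs[[i]]
    score[, pr[1]] <- score[, pr[1]] + stats::plogis(f)
    score[, pr[2]] <- score[, pr[2]] + stats::plogis(-f)
  }
  score / rowSums(score)
}

# ---- random forest ---------------------------------------------------------

rf_fit <- function(X, y, spec) {
  n <- nrow(X); p <- ncol(X)
  mtry <- spec$mtry %||% max(1L, floor(sqrt(p)))
  trees <- vector("list", spec$n_trees)
  for (t in seq_len(spec$n_trees)) {
    boot <- sample_int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(X[boot, , drop = FALSE], as.integer(y[boot]),
                            nlevels(y), mtry, spec$min_node, depth = 0L)
  }
  list(trees = trees, levels = levels(y))
}

# CART with Gini impurity; leaves store class proportions.
grow_tree <- function(X, yi, n_class, mtry, min_node, depth) {
  counts <- tabulate(yi, n_class)
  if (length(yi) < min_node || depth >= 20L || sum(counts > 0) == 1L) {
    return(list(leaf = TRUE, prob = counts / sum(counts)))
  }
  feats <- sample_int(ncol(X), min(mtry, ncol(X)))
  best <- list(gain = 0)
  parent_gini <- 1 - sum((counts / sum(counts))^2)
  for (f in feats) {
    v <- X[, f]
    ord <- order(v)
    vs <- v[ord]; ys <- yi[ord]
    distinct <- which(diff(vs) > 0)
    if (!length(distinct)) next
    left_counts <- matrix(0, length(vs), n_class)
    for (g in seq_len(n_class)) left_counts[, g] <- cumsum(ys == g)
    nl <- seq_along(vs)
    total <- left_counts[length(vs), ]
    gl <- 1 - rowSums((left_counts / nl)^2)
    right <- sweep(-left_counts, 2, total, `+`)
    nr <- length(vs) - nl
    gr <- 1 - rowSums((right / pmax(nr, 1))^2)
    w_gini <- (nl * gl + nr * gr) / length(vs)
    cand <- distinct
    gains <- parent_gini - w_gini[cand]
    bi <- which.max(gains)
    if (gains[bi] > best$gain + 1e-12) {
      best <- list(gain = gains[bi], feat = f,
                   cut = (vs[cand[bi]] + vs[cand[bi] + 1L]) / 2)
    }
  }
  if (best$gain <= 0) {
    return(list(leaf = TRUE, prob = counts / sum(counts)))
  }
  go_left <- X[, best$feat] <= best$cut
  list(
    leaf = FALSE, feat = best$feat, cut = best$cut,
    left = grow_tree(X[go_left, , drop = FALSE], yi[go_left], n_class, mtry,
                     min_node, depth + 1L),
    right = grow_tree(X[!go_left, , drop = FALSE], yi[!go_left], n_class, mtry,
                      min_node, depth + 1L)
  )
}

tree_prob <- function(tree, X) {
  n <- nrow(X)
  out <- matrix(0, n, length(tree_first_leaf(tree)))
  assign_rows <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) {
      out[rows, ] <<- matrix(node$prob, length(rows), length(node$prob), byrow = TRUE)
    } else {
      go <- X[rows, node$feat] <= node$cut
      assign_rows(node$left, rows[go])
      assign_rows(node$right, rows[!go])
    }
  }
  assign_rows(tree, seq_len(n))
  out
}

tree_first_leaf <- function(node) {
  while (!node$leaf) node <- node$left
  node$prob
}

rf_prob <- function(fit, X) {
  P <- matrix(0, nrow(X), length(fit$levels))
  for (tr in fit$trees) P <- P + tree_prob(tr, X)
  P / length(fit$trees)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}
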