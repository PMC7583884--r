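#' Top base classifiers for stacking
#'
#' Ranks the classifier kinds in a grid by their best achieved test accuracy
#' (one pipeline per kind — the kind's best cell) and returns the top `k`
#' pipeline ids. Ties break by train accuracy, then lexicographically.
#'
#' @param grid a [run_grid()] result, or its `table`.
#' @param k number of base classifiers (default 3).
#' @param mode restrict the ranking to one mode label (default: all rows).
#' @return Character vector of `k` cell ids (`mode:pipeline`).
#' @export
select_top_bases <- function(grid, k = 3L, mode = NULL) {
  tab <- if (inherits(grid, "grid_results")) grid$table else grid
  if (!is.null(mode)) tab <- tab[tab$mode == mode, , drop = FALSE]
  tab <- tab[!is.na(tab$test_accuracy), , drop = FALSE]
  kinds <- unique(tab$classifier)
  if (length(kinds) < k) {
    stop_bad("need >= ", k, " distinct classifier kinds; got ", length(kinds))
  }
  best_rows <- do.call(rbind, lapply(split(tab, tab$classifier), function(d) {
    d[order(-d$test_accuracy, -d$train_accuracy, d$pipeline), ][1L, ]
  }))
  best_rows <- best_rows[order(-best_rows$test_accuracy, -best_rows$train_accuracy,
                               best_rows$classifier), ]
  paste(best_rows$mode[seq_len(k)], best_rows$pipeline[seq_len(k)], sep = ":")
}

#' Out-of-fold meta-features
#'
#' The first stacking layer: for each base classifier, the training rows get
#' the class probabilities predicted by the fold model that was *not* trained
#' on them (out-of-fold, so the meta-learner never sees leaked information),
#' and the test rows get the average of all fold models' probabilities. Folds
#' are stratified by class so every fold model sees all classes.
#'
#' @param base_specs list of [classifier_spec()] (typically 3).
#' @param X_train,y_train training features and factor labels.
#' @param X_test test features.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param fold_assignment optional integer vector in `1:folds`, one entry per
#'   training row, overriding the seeded stratified assignment. With a fixed
#'   assignment, row i's meta-features provably cannot depend on row i's own
#'   label (its fold model never sees it) — the handle the leakage tests use.
#' @return List with `M_train` (n_train x k*n_classes), `M_test`,
#'   `fold_assignment`, and `fold_models` (per base, one model per fold).
#' @export
oof_meta_features <- function(base_specs, X_train, y_train, X_test,
                              folds = 5L, seed = 1L, fold_assignment = NULL) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y_train <- droplevels(as.factor(y_train))
  n <- nrow(X_train)
  folds <- as.integer(folds)
  if (n < folds) stop_bad("need n_train >= folds")
  fold_of <- fold_assignment %||% stratified_folds(y_train, folds, seed)
  if (length(fold_of) != n || !all(fold_of %in% seq_len(folds))) {
    stop_bad("fold_assignment must map every training row into 1..folds")
  }
  for (f in seq_len(folds)) {
    if (nlevels(droplevels(y_train[fold_of != f])) < nlevels(y_train)) {
      stop_bad("training fold ", f, " is missing a class; use stratified folds")
    }
  }
  n_class <- nlevels(y_train)
  k <- length(base_specs)
  M_train <- matrix(0, n, k * n_class)
  M_test <- matrix(0, nrow(X_test), k * n_class)
  fold_models <- vector("list", k)
  for (bi in seq_len(k)) {
    cols <- (bi - 1L) * n_class + seq_len(n_class)
    models <- vector("list", folds)
    for (f in seq_len(folds)) {
      hold <- which(fold_of == f)
      m <- fit_classifier(base_specs[[bi]], X_train[-hold, , drop = FALSE],
                          y_train[-hold])
      models[[f]] <- m
      M_train[hold, cols] <- predict_prob(m, X_train[hold, , drop = FALSE])
      M_test[, cols] <- M_test[, cols] + predict_prob(m, X_test) / folds
    }
    fold_models[[bi]] <- models
  }
  colnames(M_train) <- colnames(M_test) <-
    paste0(rep(paste0("base", seq_len(k)), each = n_class), "_",
           rep(levels(y_train), k))
  list(M_train = M_train, M_test = M_test, fold_assignment = fold_of,
       fold_models = fold_models, levels = levels(y_train))
}

# Stratified fold assignment: within each class, folds are dealt round-robin
# over a random permutation. Errors if any class has fewer members than would
# leave every training fold with all classes.
stratified_folds <- function(y, folds, seed) {
  y <- droplevels(as.factor(y))
  if (any(table(y) < folds)) {
    small <- names(table(y))[table(y) < folds]
    if (any(table(y) < 2L)) {
      stop_bad("class ", paste(small, collapse = ", "),
               " too small for ", folds, "-fold stratification")
    }
  }
  with_seed(seed, {
    fold_of <- integer(length(y))
    for (g in levels(y)) {
      idx <- which(y == g)
      fold_of[idx[sample_int(length(idx), length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
    fold_of
  })
}

#' Fit the stacking meta-learner and evaluate
#'
#' The second stacking layer: fits `meta_spec` (default: the linear Gaussian
#' discriminant, DAC) on the out-of-fold meta-features and reports accuracy
#' on the training and test meta-features.
#'
#' @param meta_spec a [classifier_spec()] for the meta-learner.
#' @param M_train,y_train,M_test,y_test meta-features and labels.
#' @return A `grid_cell` (same contract as [train_and_eval()]).
#' @export
stack_fit_predict <- function(meta_spec, M_train, y_train, M_test, y_test) {
  train_and_eval(meta_spec, M_train, y_train, M_test, y_test)
}

#' Two-layer stacking ensemble
#'
#' Convenience wrapper tying the two layers together on one feature set:
#' out-of-fold meta-features for the base classifiers, then the meta-learner.
#'
#' @param base_specs list of base [classifier_spec()]s (typically the top 3
#'   kinds from the grid).
#' @param X_train,y_train,X_test,y_test features and labels.
#' @param meta_spec meta-learner spec (default linear DAC).
#' @param folds,seed fold count and seed for the out-of-fold layer.
#' @return Object of class `stacking_model`: the meta `grid_cell` plus the
#'   meta-features, fold models and configuration.
#' @export
stack_ensemble <- function(base_specs, X_train, y_train, X_test, y_test,
                           meta_spec = classifier_spec("DAC"), folds = 5L,
                           seed = 1L) {
  mf <- oof_meta_features(base_specs, X_train, y_train, X_test, folds, seed)
  cell <- stack_fit_predict(meta_spec, mf$M_train, y_train, mf$M_test, y_test)
  structure(
    list(cell = cell, meta_features = mf, base_specs = base_specs,
         meta_spec = meta_spec, folds = folds, seed = seed),
    class = "stacking_model"
  )
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("<stacking_model: bases %s -> %s, train %.2f%%, test %.2f%%>\n",
              paste(vapply(x$base_specs, `[[`, "", "kind"), collapse = "+"),
              x$meta_spec$kind,
              100 * x$cell$train_accuracy, 100 * x$cell$test_accuracy))
  invisible(x)
}

#' @export
predict.stacking_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  mf <- object$meta_features
  n_class <- length(mf$levels)
  M <- matrix(0, nrow(newdata), length(object$base_specs) * n_class)
  for (bi in seq_along(object$base_specs)) {
    cols <- (bi - 1L) * n_class + seq_len(n_class)
    for (m in mf$fold_models[[bi]]) {
      M[, cols] <- M[, cols] + predict_prob(m, newdata) / object$folds
    }
  }
  predict(object$cell$model, M)
}
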