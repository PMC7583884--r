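#' Stratified train/test split
#'
#' Random per-grade split at the study's 71.43/28.57 ratio: within each class
#' the training count is `round(train_fraction * n_class)`; the split is
#' disjoint and exhaustive. 280 balanced samples yield 200 train / 80 test
#' (50/20 per grade).
#'
#' @param y factor of class labels (or an `egg_cohort`, split on its grades).
#' @param train_fraction fraction in (0, 1); default 0.7143.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_fraction = 0.7143, seed = 1L) {
  if (inherits(y, "egg_cohort")) y <- y$records$grade
  y <- droplevels(as.factor(y))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_bad("train_fraction must lie strictly between 0 and 1")
  }
  counts <- table(y)
  if (any(counts < 2L)) {
    stop_bad("every class needs >= 2 samples; got ",
             paste(names(counts)[counts < 2], collapse = ", "))
  }
  with_seed(seed, {
    train <- integer(0)
    for (g in levels(y)) {
      idx <- which(y == g)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)   # never empty either side
      train <- c(train, idx[sample_int(length(idx), n_tr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

#' Train one classifier and evaluate both sets
#'
#' @param spec a [classifier_spec()].
#' @param X_train,y_train,X_test,y_test features and factor labels.
#' @return Object of class `grid_cell`: train/test accuracy, train/test
#'   confusion matrices (true class in rows), sample counts, and the fitted
#'   model. Test accuracy is by construction an integer multiple of
#'   `1/n_test`.
#' @export
train_and_eval <- function(spec, X_train, y_train, X_test, y_test) {
  y_train <- droplevels(as.factor(y_train))
  y_test <- factor(y_test, levels = levels(y_train))
  model <- fit_classifier(spec, X_train, y_train)
  pred_tr <- predict(model, X_train)
  pred_te <- predict(model, X_test)
  conf_tr <- table(true = y_train, predicted = pred_tr)
  conf_te <- table(true = y_test, predicted = pred_te)
  structure(
    list(spec = spec, model = model,
         train_accuracy = mean(pred_tr == y_train),
         test_accuracy = mean(pred_te == y_test),
         confusion_train = conf_tr, confusion = conf_te,
         n_train = length(y_train), n_test = length(y_test)),
    class = "grid_cell"
  )
}

#' @export
print.grid_cell <- function(x, ...) {
  cat(sprintf("<grid_cell: %s, train %.2f%%, test %.2f%%>\n",
              x$spec$kind, 100 * x$train_accuracy, 100 * x$test_accuracy))
  invisible(x)
}

# Feature matrices after one (preprocessor, selector) pipeline, fitted on the
# training rows only. Returns train/test matrices plus the selection result.
build_features <- function(train_sp, test_sp, prep_id, selector_id, y_train,
                           seed, selector_args = list()) {
  prep <- pp_fit(preprocessor(prep_id), train_sp)
  tr <- pp_transform(prep, train_sp)
  te <- pp_transform(prep, test_sp)
  y_num <- as.numeric(as.integer(as.factor(y_train)))
  if (selector_id == "pca") {
    sel <- do.call(pca_reduce, c(list(tr, te), selector_args))
    list(X_train = sel$projected_features, X_test = sel$projected_test,
         selection = sel, prep = prep)
  } else if (selector_id == "spa") {
    sel <- do.call(spa_select, c(list(tr, y_num, seed = seed), selector_args))
    idx <- sel$selected_band_indices
    list(X_train = tr$X[, idx, drop = FALSE], X_test = te$X[, idx, drop = FALSE],
         selection = sel, prep = prep)
  } else if (selector_id == "cars") {
    sel <- do.call(cars_select, c(list(tr, y_num, seed = seed), selector_args))
    idx <- sel$selected_band_indices
    list(X_train = tr$X[, idx, drop = FALSE], X_test = te$X[, idx, drop = FALSE],
         selection = sel, prep = prep)
  } else if (selector_id == "none") {
    list(X_train = tr$X, X_test = te$X, selection = NULL, prep = prep)
  } else {
    stop_bad("unknown selector: ", selector_id)
  }
}

#' Run the preprocessing x selection x classifier grid
#'
#' Full Cartesian sweep over acquisition modes, preprocessing methods,
#' wavelength selectors and classifier kinds. Preprocessing and selection are
#' fitted on the training rows only; each cell reports train/test accuracy.
#' Failed cells are recorded (with the error message) and the sweep
#' continues. The best model per mode is the cell with the highest test
#' accuracy, ties broken by higher train accuracy, then lexicographic
#' pipeline id.
#'
#' @param cohort an [simulate_cohort()] result (or any `egg_cohort`).
#' @param modes mode labels to sweep (default: all modes in the cohort).
#' @param preprocessors character vector of [preprocessor()] ids.
#' @param selectors character vector among `"pca"`, `"spa"`, `"cars"`, `"none"`.
#' @param classifiers list of [classifier_spec()] or character kinds.
#' @param train_fraction,seed split fraction and master seed.
#' @param selector_args named list of extra arguments per selector id,
#'   e.g. `list(cars = list(n_runs = 50))`.
#' @return Object of class `grid_results`: `table` (one row per cell),
#'   `cells` (the fitted artifacts), `splits` per mode, and `best_per_mode`.
#' @export
run_grid <- function(cohort, modes = NULL, preprocessors = "snv",
                     selectors = "pca", classifiers = list("DAC", "KNN", "LDA"),
                     train_fraction = 0.7143, seed = 1L,
                     selector_args = list()) {
  stopifnot(inherits(cohort, "egg_cohort"))
  modes <- modes %||% names(cohort$spectra)
  if (!length(modes) || !length(preprocessors) || !length(selectors) ||
      !length(classifiers)) {
    stop_bad("need at least one mode, preprocessor, selector and classifier")
  }
  classifiers <- lapply(classifiers, function(cl) {
    if (inherits(cl, "classifier_spec")) cl else classifier_spec(cl, seed = seed)
  })
  y <- cohort$records$grade
  rows <- list()
  cells <- list()
  splits <- list()
  # one egg is one sample: the same train/test split of eggs is shared by all
  # modes, so per-mode accuracies are paired comparisons on identical test eggs
  shared_split <- stratified_split(y, train_fraction, seed = child_seed(seed, 1L))
  for (mi in seq_along(modes)) {
    mode_lbl <- modes[[mi]]
    sp_all <- cohort_spectra(cohort, mode_lbl)
    split <- shared_split
    splits[[mode_lbl]] <- split
    train_sp <- spectra_matrix(sp_all$X[split$train, , drop = FALSE],
                               sp_all$wavelengths_nm)
    test_sp <- spectra_matrix(sp_all$X[split$test, , drop = FALSE],
                              sp_all$wavelengths_nm)
    y_tr <- y[split$train]; y_te <- y[split$test]
    for (prep_id in preprocessors) {
      for (sel_id in selectors) {
        feats <- tryCatch(
          build_features(train_sp, test_sp, prep_id, sel_id, y_tr,
                         seed = child_seed(seed, 1000 + mi),
                         selector_args = selector_args[[sel_id]] %||% list()),
          error = function(e) e
        )
        for (cl in classifiers) {
          pid <- paste(prep_id, sel_id, cl$kind, sep = "-")
          cell_id <- paste(mode_lbl, pid, sep = ":")
          if (cell_id %in% names(cells) || any(names(rows) == cell_id)) {
            cell_id <- paste0(cell_id, "#", length(rows) + 1L)
          }
          if (inherits(feats, "error")) {
            rows[[cell_id]] <- data.frame(
              mode = mode_lbl, preprocessor = prep_id, selector = sel_id,
              classifier = cl$kind, pipeline = pid,
              train_accuracy = NA_real_, test_accuracy = NA_real_,
              n_train = length(y_tr), n_test = length(y_te),
              error = conditionMessage(feats), stringsAsFactors = FALSE)
            next
          }
          cell <- tryCatch(
            train_and_eval(cl, feats$X_train, y_tr, feats$X_test, y_te),
            error = function(e) e
          )
          if (inherits(cell, "error")) {
            rows[[cell_id]] <- data.frame(
              mode = mode_lbl, preprocessor = prep_id, selector = sel_id,
              classifier = cl$kind, pipeline = pid,
              train_accuracy = NA_real_, test_accuracy = NA_real_,
              n_train = length(y_tr), n_test = length(y_te),
              error = conditionMessage(cell), stringsAsFactors = FALSE)
            next
          }
          cell$selection <- feats$selection
          cell$prep <- feats$prep
          cells[[cell_id]] <- cell
          rows[[cell_id]] <- data.frame(
            mode = mode_lbl, preprocessor = prep_id, selector = sel_id,
            classifier = cl$kind, pipeline = pid,
            train_accuracy = cell$train_accuracy,
            test_accuracy = cell$test_accuracy,
            n_train = cell$n_train, n_test = cell$n_test,
            error = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(
    list(table = tab, cells = cells, splits = splits,
         best_per_mode = best_per_mode_table(tab)),
    class = "grid_results"
  )
}

# Best cell per mode: max test accuracy, ties by train accuracy then
# lexicographic pipeline id.
best_per_mode_table <- function(tab) {
  ok <- tab[!is.na(tab$test_accuracy), , drop = FALSE]
  if (!nrow(ok)) return(ok)
  do.call(rbind, lapply(split(ok, ok$mode), function(d) {
    d <- d[order(-d$test_accuracy, -d$train_accuracy, d$pipeline), , drop = FALSE]
    d[1L, c("mode", "pipeline", "preprocessor", "selector", "classifier",
            "train_accuracy", "test_accuracy")]
  }))
}

#' @export
print.grid_results <- function(x, ...) {
  cat(sprintf("<grid_results: %d cell(s) over %d mode(s), %d failed>\n",
              nrow(x$table), length(unique(x$table$mode)),
              sum(is.na(x$table$test_accuracy))))
  if (nrow(x$best_per_mode)) {
    b <- x$best_per_mode
    b$train_accuracy <- sprintf("%.2f%%", 100 * b$train_accuracy)
    b$test_accuracy <- sprintf("%.2f%%", 100 * b$test_accuracy)
    print(b, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.grid_results <- function(object, ...) {
  tab <- object$table
  cat("accuracy by classifier (test, %):\n")
  print(round(100 * tapply(tab$test_accuracy, tab$classifier, max, na.rm = TRUE), 2))
  invisible(object$table)
}

#' Export a grid table in the percent layout of the study tables
#'
#' @param grid a `grid_results`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  tab <- grid$table
  tab$train_accuracy <- round(100 * tab$train_accuracy, 2)
  tab$test_accuracy <- round(100 * tab$test_accuracy, 2)
  names(tab)[names(tab) == "train_accuracy"] <- "train_accuracy_pct"
  names(tab)[names(tab) == "test_accuracy"] <- "test_accuracy_pct"
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
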