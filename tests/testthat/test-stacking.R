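test_that("top-base selection ranks kinds by best accuracy with stated tie rules", {
  tab <- data.frame(
    mode = "scatter_0",
    preprocessor = "snv", selector = "pca",
    classifier = c("DAC", "DAC", "KNN", "RF", "NB", "LDA", "SVM"),
    pipeline = c("snv-pca-DAC", "mc-pca-DAC", "snv-pca-KNN", "snv-pca-RF",
                 "snv-pca-NB", "snv-pca-LDA", "snv-pca-SVM"),
    train_accuracy = c(0.99, 0.98, 0.97, 0.99, 0.90, 0.95, 0.94),
    test_accuracy = c(0.95, 0.96, 0.94, 0.93, 0.80, 0.85, 0.84),
    stringsAsFactors = FALSE
  )
  top <- select_top_bases(tab, k = 3)
  expect_equal(top, c("scatter_0:mc-pca-DAC", "scatter_0:snv-pca-KNN",
                      "scatter_0:snv-pca-RF"))
  expect_equal(select_top_bases(tab, k = 1), "scatter_0:mc-pca-DAC")
  expect_error(select_top_bases(tab[tab$classifier %in% c("DAC", "KNN"), ], k = 3),
               "distinct")
  # full tie -> lexicographic kinds first
  tie <- tab
  tie$test_accuracy <- 0.9; tie$train_accuracy <- 0.9
  expect_equal(sort(sub(".*-", "", select_top_bases(tie, k = 3))),
               sort(c("DAC", "KNN", "LDA")))
})

test_that("meta-features have the dimensional contract and simplex blocks", {
  blobs <- make_blobs(n_per_class = 50, sep = 2.5, sd = 1.5, seed = 1)
  sp <- stratified_split(blobs$y, seed = 2)
  specs <- lapply(c("DAC", "KNN", "LDA"), classifier_spec)
  mf <- oof_meta_features(specs, blobs$X[sp$train, ], blobs$y[sp$train],
                          blobs$X[sp$test, ], folds = 5, seed = 3)
  n_tr <- length(sp$train)
  expect_equal(dim(mf$M_train), c(n_tr, 12L))
  expect_equal(dim(mf$M_test), c(length(sp$test), 12L))
  for (b in 0:2) {
    block <- mf$M_train[, b * 4 + 1:4]
    expect_equal(rowSums(block), rep(1, n_tr), tolerance = 1e-9)
  }
  # every training sample sits in exactly one validation fold
  expect_equal(sort(unique(mf$fold_assignment)), 1:5)
  expect_equal(length(mf$fold_assignment), n_tr)
})

test_that("a base with uniform probabilities yields all-1/4 meta-features", {
  # Gaussian NB on identical class distributions with equal priors is uniform:
  # constant features per class
  n <- 40
  X <- matrix(1, n, 2) + 0   # constant features
  y <- factor(rep(grade_levels(), each = 10), levels = grade_levels())
  mf <- oof_meta_features(list(classifier_spec("NB")), X, y, X[1:4, ],
                          folds = 5, seed = 4)
  expect_equal(unname(mf$M_train), matrix(0.25, n, 4), tolerance = 1e-9)
  expect_equal(unname(mf$M_test), matrix(0.25, 4, 4), tolerance = 1e-9)
})

test_that("out-of-fold meta-features never leak a row's own label", {
  blobs <- make_blobs(n_per_class = 25, sep = 2, sd = 1.5, seed = 5)
  specs <- list(classifier_spec("DAC"), classifier_spec("KNN"),
                classifier_spec("LDA"))
  base <- oof_meta_features(specs, blobs$X, blobs$y, blobs$X[1:5, ],
                            folds = 5, seed = 6)
  set.seed(7)
  for (i in sample(nrow(blobs$X), 10)) {
    y_flip <- blobs$y
    lv <- levels(y_flip)
    y_flip[i] <- lv[(as.integer(y_flip[i]) %% 4) + 1]
    flipped <- oof_meta_features(specs, blobs$X, y_flip, blobs$X[1:5, ],
                                 folds = 5, seed = 6,
                                 fold_assignment = base$fold_assignment)
    expect_equal(flipped$M_train[i, ], base$M_train[i, ], tolerance = 1e-12)
  }
})

test_that("stacking beats every base when their errors are complementary", {
  # three bases, each perfect on a disjoint block of classes and uninformative
  # elsewhere, constructed directly as meta-features
  set.seed(8)
  n <- 120
  y <- factor(rep(grade_levels(), each = 30), levels = grade_levels())
  make_meta <- function(known) {
    M <- matrix(0.25, n, 4)
    for (i in seq_len(n)) {
      if (y[i] %in% known) {
        M[i, ] <- 0.02
        M[i, as.integer(y[i])] <- 0.94
      }
    }
    M
  }
  M <- cbind(make_meta(c("AA", "A")), make_meta(c("B1", "A")),
             make_meta(c("B2", "B1")))
  # base accuracies: each base alone classifies only its known block
  base_acc <- vapply(1:3, function(b) {
    block <- M[, (b - 1) * 4 + 1:4]
    mean(max.col(block, ties.method = "first") == as.integer(y))
  }, numeric(1))
  sp <- stratified_split(y, seed = 9)
  suppressMessages(
    cell <- stack_fit_predict(classifier_spec("DAC"), M[sp$train, ], y[sp$train],
                              M[sp$test, ], y[sp$test])
  )
  expect_gte(cell$test_accuracy, max(base_acc))
  expect_equal(cell$test_accuracy, 1.0)
})

test_that("three identical bases stack to the base accuracy", {
  blobs <- make_blobs(n_per_class = 40, sep = 2.2, sd = 1.5, seed = 10)
  sp <- stratified_split(blobs$y, seed = 11)
  Xtr <- blobs$X[sp$train, ]; Xte <- blobs$X[sp$test, ]
  ytr <- blobs$y[sp$train]; yte <- blobs$y[sp$test]
  single <- train_and_eval(classifier_spec("DAC"), Xtr, ytr, Xte, yte)
  suppressMessages(
    st <- stack_ensemble(lapply(c("DAC", "DAC", "DAC"), classifier_spec),
                         Xtr, ytr, Xte, yte, folds = 5, seed = 12)
  )
  quantum <- 1 / single$n_test
  expect_lte(abs(st$cell$test_accuracy - single$test_accuracy), 2 * quantum + 1e-12)
})

test_that("the full stack is bit-for-bit reproducible under a fixed seed", {
  blobs <- make_blobs(n_per_class = 20, sep = 2.5, sd = 1.2, seed = 13)
  sp <- stratified_split(blobs$y, seed = 14)
  run <- function() {
    suppressMessages(stack_ensemble(
      lapply(c("DAC", "KNN", "LDA"), classifier_spec),
      blobs$X[sp$train, ], blobs$y[sp$train],
      blobs$X[sp$test, ], blobs$y[sp$test], seed = 15))
  }
  a <- run(); b <- run()
  expect_identical(a$meta_features$M_train, b$meta_features$M_train)
  expect_identical(a$cell$test_accuracy, b$cell$test_accuracy)
})
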