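test_that("stratified split reproduces the 71.43/28.57 design: 280 -> 200/80", {
  y <- factor(rep(grade_levels(), each = 70), levels = grade_levels())
  sp <- stratified_split(y, seed = 1)
  expect_equal(length(sp$train), 200L)
  expect_equal(length(sp$test), 80L)
  expect_equal(unname(table(y[sp$train])), rep(50L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(y[sp$test])), rep(20L, 4), ignore_attr = TRUE)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
})

test_that("degenerate split fractions and tiny classes are rejected", {
  y <- factor(rep(grade_levels(), each = 10))
  expect_error(stratified_split(y, train_fraction = 1), "between 0 and 1")
  expect_error(stratified_split(y, train_fraction = 0), "between 0 and 1")
  y2 <- factor(c(rep("AA", 10), "A"), levels = c("AA", "A"))
  expect_error(stratified_split(y2), ">= 2")
})

test_that("splits are seed-deterministic and seed-sensitive", {
  y <- factor(rep(grade_levels(), each = 25))
  expect_identical(stratified_split(y, seed = 5), stratified_split(y, seed = 5))
  s6 <- stratified_split(y, seed = 6)
  expect_false(identical(stratified_split(y, seed = 5)$train, s6$train))
  expect_equal(length(s6$train), length(stratified_split(y, seed = 5)$train))
})

test_that("all six classifiers separate well-separated blobs perfectly", {
  blobs <- make_blobs(n_per_class = 15, sep = 8, sd = 0.5, seed = 1)
  test <- make_blobs(n_per_class = 10, sep = 8, sd = 0.5, seed = 2)
  for (kind in c("DAC", "KNN", "SVM", "LDA", "NB", "RF")) {
    cell <- train_and_eval(classifier_spec(kind, seed = 3), blobs$X, blobs$y,
                           test$X, test$y)
    expect_equal(cell$test_accuracy, 1.0, info = kind)
    expect_equal(sum(diag(cell$confusion)), 40L, info = kind)
  }
})

test_that("class probabilities are simplex-valued for every classifier", {
  blobs <- make_blobs(n_per_class = 12, sep = 4, sd = 1.5, seed = 4)
  Xnew <- make_blobs(n_per_class = 5, sep = 4, sd = 1.5, seed = 5)$X
  for (kind in c("DAC", "KNN", "SVM", "LDA", "NB", "RF")) {
    m <- fit_classifier(classifier_spec(kind, seed = 6), blobs$X, blobs$y)
    P <- predict_prob(m, Xnew)
    expect_equal(dim(P), c(20L, 4L), info = kind)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9, info = kind)
    expect_true(all(P >= 0), info = kind)
  }
})

test_that("shuffled labels give chance-level accuracy within binomial bounds", {
  set.seed(7)
  n <- 160
  X <- matrix(rnorm(n * 3), n, 3)
  y <- factor(rep(grade_levels(), each = n / 4))
  y_shuffled <- sample(y)
  sp <- stratified_split(y_shuffled, seed = 8)
  cell <- train_and_eval(classifier_spec("DAC"), X[sp$train, ], y_shuffled[sp$train],
                         X[sp$test, ], y_shuffled[sp$test])
  # 99% binomial band around 0.25 for n_test
  band <- 2.576 * sqrt(0.25 * 0.75 / cell$n_test)
  expect_lt(abs(cell$test_accuracy - 0.25), band + 1e-9)
})

test_that("test accuracy is always an integer multiple of 1/n_test", {
  blobs <- make_blobs(n_per_class = 20, sep = 3, sd = 2, seed = 9)
  sp <- stratified_split(blobs$y, seed = 10)
  cell <- train_and_eval(classifier_spec("KNN"), blobs$X[sp$train, ],
                         blobs$y[sp$train], blobs$X[sp$test, ], blobs$y[sp$test])
  expect_equal(cell$test_accuracy * cell$n_test,
               round(cell$test_accuracy * cell$n_test), tolerance = 1e-12)
})

test_that("DAC matches MASS lda posteriors on well-conditioned data", {
  skip_if_not_installed("MASS")
  blobs <- make_blobs(n_per_class = 25, sep = 3, sd = 1, seed = 11)
  m <- fit_classifier(classifier_spec("DAC"), blobs$X, blobs$y)
  P <- predict_prob(m, blobs$X)
  ref <- MASS::lda(blobs$X, blobs$y)
  Pref <- predict(ref, blobs$X)$posterior
  expect_lt(max(abs(P - Pref)), 1e-6)
})

test_that("quadratic DAC matches MASS qda on per-class covariances", {
  skip_if_not_installed("MASS")
  set.seed(12)
  X <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(60, 3, 2), 30, 2))
  y <- factor(rep(c("AA", "A"), each = 30), levels = c("AA", "A"))
  m <- fit_classifier(classifier_spec("DAC", discriminant = "quadratic"), X, y)
  Pref <- predict(MASS::qda(X, y), X)$posterior
  expect_lt(max(abs(predict_prob(m, X) - Pref)), 1e-6)
})

test_that("singular covariance under DAC is shrunk, not fatal", {
  set.seed(13)
  X <- cbind(rnorm(40), rnorm(40))
  X <- cbind(X, X[, 1] + X[, 2])          # exactly collinear third feature
  y <- factor(rep(c("AA", "A"), 20), levels = c("AA", "A"))
  expect_message(m <- fit_classifier(classifier_spec("DAC"), X, y), "shrunk")
  expect_s3_class(m, "egg_classifier")
})

test_that("the grid sweeps all cells, tolerates failures, and ranks the best", {
  coh <- simulate_cohort(28, 2, modes = all_modes()[c("scatter_0", "reflection")],
                         config = tiny_config(14))
  suppressMessages(
    grid <- run_grid(coh, preprocessors = c("snv", "mc"), selectors = "pca",
                     classifiers = list("DAC", "KNN", "LDA"), seed = 15)
  )
  expect_equal(nrow(grid$table), 2 * 2 * 1 * 3)
  expect_true(all(!is.na(grid$table$test_accuracy)))
  expect_equal(nrow(grid$best_per_mode), 2L)
  # best row really is the max by (test, train, pipeline)
  for (m in unique(grid$table$mode)) {
    d <- grid$table[grid$table$mode == m, ]
    expect_equal(grid$best_per_mode[grid$best_per_mode$mode == m, "test_accuracy"],
                 max(d$test_accuracy))
  }
})

test_that("grid results are deterministic and duplicate classifiers agree", {
  coh <- simulate_cohort(8, 3, modes = all_modes()["scatter_0"],
                         config = tiny_config(16))
  run <- function() {
    suppressMessages(run_grid(coh, preprocessors = "snv", selectors = "pca",
                              classifiers = list("DAC", "DAC2" = "DAC", "KNN"),
                              seed = 17)$table)
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1, t2)
  dac_rows <- t1[t1$classifier == "DAC", ]
  expect_equal(dac_rows$test_accuracy[1], dac_rows$test_accuracy[2])
})

test_that("a 1x1x1 grid returns a single cell that is its own best", {
  coh <- simulate_cohort(8, 2, modes = all_modes()["scatter_0"],
                         config = tiny_config(18))
  grid <- run_grid(coh, preprocessors = "snv", selectors = "none",
                   classifiers = list("KNN"), seed = 19)
  expect_equal(nrow(grid$table), 1L)
  expect_equal(grid$best_per_mode$pipeline, grid$table$pipeline)
})

test_that("fitted state never depends on test rows (leakage hash check)", {
  coh <- simulate_cohort(8, 4, modes = all_modes()["scatter_0"],
                         config = tiny_config(20))
  sp_all <- cohort_spectra(coh, "scatter_0")
  y <- coh$records$grade
  split <- stratified_split(y, seed = 21)
  tr <- spectra_matrix(sp_all$X[split$train, , drop = FALSE], sp_all$wavelengths_nm)
  te <- spectra_matrix(sp_all$X[split$test, , drop = FALSE], sp_all$wavelengths_nm)
  te_mut <- spectra_matrix(te$X * 3 + 0.5, sp_all$wavelengths_nm)
  f1 <- ovospec:::build_features(tr, te, "snv", "pca", y[split$train], seed = 22)
  f2 <- ovospec:::build_features(tr, te_mut, "snv", "pca", y[split$train], seed = 22)
  # fitted artifacts identical; only the projected test rows differ
  expect_identical(f1$prep$fitted_state, f2$prep$fitted_state)
  expect_identical(f1$selection$diagnostics$loadings, f2$selection$diagnostics$loadings)
  expect_identical(f1$X_train, f2$X_train)
})
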