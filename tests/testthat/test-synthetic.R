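test_that("acquisition modes validate their geometry", {
  expect_equal(length(all_modes()), 9L)
  expect_error(acquisition_mode("scatter"), "angle_deg")
  expect_error(acquisition_mode("scatter", 15), "angle_deg")
  expect_error(acquisition_mode("reflection", 10), "only for")
  expect_equal(mode_label(acquisition_mode("scatter", 40)), "scatter_40")
})

test_that("generator config rejects invalid stated-world parameters", {
  expect_error(generator_config(n_bands = 4), "n_bands")
  expect_error(generator_config(wavelength_min_nm = 900, wavelength_max_nm = 500),
               "wavelength")
  expect_error(generator_config(scatter_fraction_at_0 = 1.2), "fractions")
})

test_that("a 28-day, 10-egg cohort has 280 records balanced over grades", {
  coh <- simulate_cohort(28, 10, modes = list(scatter0), config = tiny_config(3))
  expect_equal(nrow(coh$records), 280L)
  expect_equal(unname(table(coh$records$grade)), rep(70L, 4), ignore_attr = TRUE)
  # Haugh formula round-trips through the stored weight/height
  expect_equal(haugh_unit(coh$records$protein_height_mm, coh$records$weight_g),
               coh$records$haugh, tolerance = 1e-9)
  expect_true(all(coh$records$weight_g >= 31.5 & coh$records$weight_g <= 46.6))
  expect_error(simulate_cohort(29, 1, list(), tiny_config()), "four weeks")
})

test_that("zero Haugh noise reproduces the degradation line exactly", {
  cfg <- tiny_config(5, haugh_noise_sd = 0)
  coh <- simulate_cohort(28, 2, modes = list(), config = cfg)
  expect_equal(coh$records$haugh, 85.70 - 1.75 * coh$records$day, tolerance = 1e-12)
})

test_that("cohorts are deterministic in the seed", {
  a <- simulate_cohort(5, 3, list(scatter0), tiny_config(9))
  b <- simulate_cohort(5, 3, list(scatter0), tiny_config(9))
  expect_identical(a, b)
  c2 <- simulate_cohort(5, 3, list(scatter0), tiny_config(10))
  expect_false(identical(a$records$haugh, c2$records$haugh))
})

test_that("spectral freshness contrast is stronger at 0 deg than in reflection", {
  cfg <- clean_config()
  refl <- acquisition_mode("reflection")
  d0 <- abs(egg_spectrum(80, scatter0, cfg)$values -
            egg_spectrum(40, scatter0, cfg)$values)
  dr <- abs(egg_spectrum(80, refl, cfg)$values -
            egg_spectrum(40, refl, cfg)$values)
  expect_gt(mean(d0), mean(dr))
})

test_that("spectra are deterministic when all distortion sds are zero", {
  cfg <- clean_config()
  expect_identical(egg_spectrum(70, scatter0, cfg)$values,
                   egg_spectrum(70, scatter0, cfg)$values)
})

test_that("MSC of corrected spectra recovers the undistorted spectrum in expectation", {
  cfg <- tiny_config(21)
  truth <- ovospec:::egg_spectrum_clean(70, scatter0, cfg)$values
  set.seed(77)
  draws <- t(replicate(200, egg_spectrum(70, scatter0, cfg)$values))
  sp <- spectra_matrix(draws, ovospec:::gen_wavelengths(cfg))
  prep <- pp_fit(preprocessor("msc"), sp)
  corrected <- pp_transform(prep, sp)$X
  expect_lt(max(abs(colMeans(corrected) - truth)), 3 * cfg$channel_noise_sd)
})

test_that("grade information (Fisher ratio) decreases with incident angle and is lowest in reflection", {
  angles <- seq(0, 60, by = 10)
  modes <- c(lapply(angles, function(a) acquisition_mode("scatter", a)),
             list(acquisition_mode("reflection")))
  ratios <- matrix(0, 10, length(modes))
  for (s in 1:10) {
    coh <- simulate_cohort(28, 2, modes = modes, config = tiny_config(100 + s))
    ratios[s, ] <- vapply(names(coh$spectra), function(lbl) {
      # informativeness is measured after scatter correction (SNV), since the
      # multiplicative/additive distortions are mode-independent nuisance
      sp <- spectra_matrix(coh$spectra[[lbl]], coh$wavelengths_nm)
      ovospec:::fisher_ratio(pp_transform(preprocessor("snv"), sp)$X,
                             coh$records$grade)
    }, numeric(1))
  }
  mean_ratio <- colMeans(ratios)
  expect_true(all(diff(mean_ratio[seq_along(angles)]) < 0))      # decreasing in angle
  expect_lt(mean_ratio[length(modes)], min(mean_ratio[seq_along(angles)]))
})

test_that("scene rendering honours layout bounds and overlap rules", {
  cfg <- tiny_config(n_bands = 16)
  spec <- ovospec:::egg_spectrum_clean(75, scatter0, cfg)
  expect_error(
    render_scene(list(spec), list(list(center = c(5, 32), axes = c(10, 10))),
                 c(64, 64), cfg),
    "outside"
  )
  expect_error(
    render_scene(list(spec, spec),
                 list(list(center = c(32, 30), axes = c(10, 10)),
                      list(center = c(32, 40), axes = c(10, 10))),
                 c(64, 64), cfg),
    "overlap"
  )
})

test_that("black/white correction of a rendered scene recovers shading x spectrum", {
  sc <- demo_scene(seed = 31, n = 1)
  cube <- black_white_correct(sc$raw, sc$white, sc$dark)
  ctr <- sc$layout[[1]]$center
  got <- cube$data[ctr[1], ctr[2], ]
  want <- sc$truth[[1]]$values * sc$shading[ctr[1], ctr[2]]
  expect_lt(max(abs(got - want)), 3 * sc$config$channel_noise_sd)
})

test_that("a scene with zero eggs corrects to pure background", {
  cfg <- tiny_config(n_bands = 16)
  sc <- render_scene(list(), list(), c(32, 32), cfg, seed = 4)
  cube <- black_white_correct(sc$raw, sc$white, sc$dark)
  # every pixel should be the flat background spectrum up to noise
  bg <- apply(cube$data, 3, stats::median)
  dev <- sweep(cube$data, 3, bg)
  expect_lt(max(abs(dev)), 5 * cfg$channel_noise_sd)
})

test_that("OLS on noisy cohorts recovers the degradation law (quick check)", {
  hits <- 0L
  for (s in 1:10) {
    coh <- simulate_cohort(28, 5, modes = list(), config = tiny_config(400 + s))
    fit <- fit_degradation(coh$records$day, coh$records$haugh)
    hits <- hits + (abs(fit$slope + 1.75) <= 0.15 && abs(fit$intercept - 85.70) <= 1.5)
  }
  expect_gte(hits, 9L)
})

test_that("cohort exports one row per egg x mode with band columns", {
  coh <- simulate_cohort(2, 2, modes = all_modes()[c("reflection", "scatter_0")],
                         config = tiny_config(2))
  df <- as.data.frame(coh)
  expect_equal(nrow(df), 4 * 2)
  expect_true(all(c("egg_id", "day", "haugh", "grade", "mode") %in% names(df)))
  expect_equal(sum(grepl("^nm", names(df))), 64L)
})
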