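# Shared fixtures: everything is generated in code at test time.

# A small, fast generator: fewer bands, otherwise the default stated world.
tiny_config <- function(seed = 1L, n_bands = 64L, ...) {
  generator_config(n_bands = n_bands, seed = seed, ...)
}

# Noise-free generator (all distortion sds zero).
clean_config <- function(seed = 1L, ...) {
  generator_config(n_bands = 64L, haugh_noise_sd = 0, multiplicative_sd = 0,
                   additive_sd = 0, channel_noise_sd = 0, seed = seed, ...)
}

scatter0 <- acquisition_mode("scatter", 0)

# Well-separated Gaussian class blobs for classifier tests.
make_blobs <- function(n_per_class = 20, n_class = 4, p = 2, sep = 6, sd = 1,
                       seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(n_class), function(g) {
    ctr <- sep * c(cos(2 * pi * g / n_class), sin(2 * pi * g / n_class))
    ctr <- rep_len(ctr, p)
    sweep(matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p), 2, ctr, `+`)
  }))
  y <- factor(rep(grade_levels()[seq_len(n_class)], each = n_per_class),
              levels = grade_levels()[seq_len(n_class)])
  list(X = X, y = y)
}

# A 3-egg-ellipse scene of the given image size; returns the render plus the
# true spectra used.
demo_scene <- function(seed = 1, n = 1, size = c(64, 64), config = tiny_config(seed)) {
  centers <- list(c(32, 32), c(12, 48), c(50, 12))[seq_len(n)]
  axes <- list(c(14, 10), c(7, 7), c(7, 7))[seq_len(n)]
  layout <- Map(function(ctr, ax) list(center = ctr, axes = ax), centers, axes)
  specs <- lapply(seq_len(n), function(i) {
    ovospec:::egg_spectrum_clean(80 - 10 * i, scatter0, config)
  })
  c(render_scene(specs, layout, size, config, seed = seed),
    list(truth = specs, layout = layout, config = config))
}
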