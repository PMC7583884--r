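#' Generator configuration
#'
#' Parameters of the synthetic egg-cohort and scene generator. The defaults
#' encode the stated study conditions: Haugh units decline linearly at
#' -1.75 units/day from 85.70 with a per-egg biological spread of 4 HU
#' (within the observed weekly standard deviations 3.6-5.5), egg weights are
#' uniform on 31.5-46.6 g, and spectra cover 400-1000 nm in 256 bands
#' (the VNIR camera's range at desk scale).
#'
#' Each simulated spectrum is a three-endmember mixture
#' \deqn{v(\lambda) = \alpha S_{int} + (1-\alpha-\beta) S_{shell} + \beta S_{src}}
#' where only the interior endmember \eqn{S_{int}} carries freshness
#' information (Gaussian peaks whose amplitudes are affine in
#' `(HU - 60)/30`). The scattered fraction \eqn{\alpha} decays linearly from
#' `scatter_fraction_at_0` at 0 degrees to `scatter_fraction_at_60` at
#' 60 degrees, is small for dome reflection and intermediate for
#' transmission (which also bleeds a fraction `transmission_bleed_fraction`
#' of raw source light). This makes the study's observation — freshness
#' information decreasing with incident angle and minimal for reflection — a
#' measurable property of the data rather than an assumption.
#'
#' @param n_bands number of spectral bands (>= 8).
#' @param wavelength_min_nm,wavelength_max_nm spectral range in nm.
#' @param slope_per_day,intercept Haugh-unit degradation line (units/day, units).
#' @param haugh_noise_sd per-egg Haugh-unit standard deviation around the line.
#' @param weight_range_g egg weight range in grams (uniform).
#' @param informative_centers_nm centers of the freshness-informative peaks.
#' @param peak_width_nm Gaussian width (sd) of the informative peaks, nm.
#' @param peak_base_amplitude freshness-independent part of the peak heights.
#' @param peak_haugh_amplitude amplitude change per unit of `(HU - 60)/30`;
#'   sign alternates across peaks. Chosen so that at the best geometry the
#'   spectra predict HU about as well as published reflectance calibrations
#'   (about 4 HU residual sd; see the package vignette).
#' @param scatter_fraction_at_0,scatter_fraction_at_60 interior (scattered)
#'   fraction at incident angles 0 and 60 degrees; linear in between.
#' @param reflection_scatter_fraction interior fraction under dome reflection.
#' @param transmission_scatter_fraction interior fraction under transmission.
#' @param transmission_bleed_fraction fraction of raw source light reaching the
#'   camera under transmission.
#' @param multiplicative_sd,additive_sd per-spectrum scatter distortion sds
#'   (gain ~ Normal(1, multiplicative_sd^2), offset ~ Normal(0, additive_sd^2)).
#' @param channel_noise_sd independent per-band noise sd.
#' @param seed integer seed; all generator randomness derives from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_bands = 256L,
                             wavelength_min_nm = 400,
                             wavelength_max_nm = 1000,
                             slope_per_day = -1.75,
                             intercept = 85.70,
                             haugh_noise_sd = 4.0,
                             weight_range_g = c(31.5, 46.6),
                             informative_centers_nm = c(450, 550, 680, 980),
                             peak_width_nm = 20,
                             peak_base_amplitude = 0.18,
                             peak_haugh_amplitude = 0.013,
                             scatter_fraction_at_0 = 0.9,
                             scatter_fraction_at_60 = 0.3,
                             reflection_scatter_fraction = 0.05,
                             transmission_scatter_fraction = 0.45,
                             transmission_bleed_fraction = 0.35,
                             multiplicative_sd = 0.10,
                             additive_sd = 0.05,
                             channel_noise_sd = 0.01,
                             seed = 1L) {
  cfg <- list(
    n_bands = as.integer(n_bands),
    wavelength_min_nm = wavelength_min_nm,
    wavelength_max_nm = wavelength_max_nm,
    slope_per_day = slope_per_day,
    intercept = intercept,
    haugh_noise_sd = haugh_noise_sd,
    weight_range_g = weight_range_g,
    informative_centers_nm = informative_centers_nm,
    peak_width_nm = peak_width_nm,
    peak_base_amplitude = peak_base_amplitude,
    peak_haugh_amplitude = peak_haugh_amplitude,
    scatter_fraction_at_0 = scatter_fraction_at_0,
    scatter_fraction_at_60 = scatter_fraction_at_60,
    reflection_scatter_fraction = reflection_scatter_fraction,
    transmission_scatter_fraction = transmission_scatter_fraction,
    transmission_bleed_fraction = transmission_bleed_fraction,
    multiplicative_sd = multiplicative_sd,
    additive_sd = additive_sd,
    channel_noise_sd = channel_noise_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_bands < 8L) stop_bad("n_bands must be >= 8")
  if (!(wavelength_min_nm < wavelength_max_nm)) {
    stop_bad("wavelength_min_nm must be < wavelength_max_nm")
  }
  fr <- c(scatter_fraction_at_0, scatter_fraction_at_60,
          reflection_scatter_fraction, transmission_scatter_fraction,
          transmission_bleed_fraction)
  if (any(fr < 0 | fr > 1)) stop_bad("all mixing fractions must lie in [0, 1]")
  if (transmission_scatter_fraction + transmission_bleed_fraction > 1) {
    stop_bad("transmission fractions must sum to <= 1")
  }
  if (length(weight_range_g) != 2L || diff(weight_range_g) <= 0) {
    stop_bad("weight_range_g must be an increasing pair")
  }
  if (any(c(haugh_noise_sd, multiplicative_sd, additive_sd, channel_noise_sd) < 0)) {
    stop_bad("noise sds must be non-negative")
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config: %d bands %.0f-%.0f nm, HU = %.2f %+.2f*day (sd %.1f), seed %d>\n",
    x$n_bands, x$wavelength_min_nm, x$wavelength_max_nm,
    x$intercept, x$slope_per_day, x$haugh_noise_sd, x$seed))
  invisible(x)
}

gen_wavelengths <- function(config) {
  seq(config$wavelength_min_nm, config$wavelength_max_nm,
      length.out = config$n_bands)
}

# ---- endmember spectra ------------------------------------------------------

# Interior (yolk/albumen/air-chamber) endmember: smooth baseline plus
# freshness-informative Gaussian peaks with alternating signs.
s_interior <- function(wl, haugh, config) {
  t <- (wl - config$wavelength_min_nm) /
    (config$wavelength_max_nm - config$wavelength_min_nm)
  base <- 0.40 + 0.12 * t + 0.08 * exp(-((wl - 620) / 90)^2)
  z <- (haugh - 60) / 30
  centers <- config$informative_centers_nm
  signs <- rep_len(c(1, -1), length(centers))
  scalings <- rep_len(c(1, 0.8, 1.2, 0.6), length(centers))
  v <- base
  for (j in seq_along(centers)) {
    amp <- config$peak_base_amplitude * scalings[j] +
      signs[j] * config$peak_haugh_amplitude * z
    v <- v + amp * exp(-((wl - centers[j]) / config$peak_width_nm)^2 / 2)
  }
  v
}

# Shell endmember: smooth, freshness-independent (pigment/cuticle only).
s_shell <- function(wl, config) {
  t <- (wl - config$wavelength_min_nm) /
    (config$wavelength_max_nm - config$wavelength_min_nm)
  0.50 + 0.22 * t - 0.06 * exp(-((wl - 520) / 70)^2)
}

# Raw source endmember: flat, bright.
s_source <- function(wl, config) {
  rep(0.95, length(wl))
}

# Interior/shell/source mixing fractions (alpha, beta) of a mode.
mode_fractions <- function(mode, config) {
  stopifnot(inherits(mode, "acq_mode"))
  switch(mode$kind,
    reflection = c(alpha = config$reflection_scatter_fraction, beta = 0),
    transmission = c(alpha = config$transmission_scatter_fraction,
                     beta = config$transmission_bleed_fraction),
    scatter = {
      a0 <- config$scatter_fraction_at_0
      a60 <- config$scatter_fraction_at_60
      c(alpha = a0 + (a60 - a0) * mode$angle_deg / 60, beta = 0)
    }
  )
}

#' Simulate one egg spectrum
#'
#' Mixes the interior, shell and source endmembers according to the
#' acquisition mode, then applies multiplicative gain, additive offset and
#' per-band noise (the distortions MSC/SNV/detrending are meant to remove).
#' Negative reflectances are clipped to 0; the clip count is attached as
#' attribute `"n_clipped"`. Uses the current RNG stream: callers that need
#' reproducibility should wrap in their own seed (as [simulate_cohort()] does).
#'
#' @param haugh Haugh unit of the egg (finite).
#' @param mode an [acquisition_mode()].
#' @param config a [generator_config()].
#' @return A list with `wavelengths_nm` and `values` (class `spectrum`).
#' @export
egg_spectrum <- function(haugh, mode, config = generator_config()) {
  if (!is.finite(haugh)) stop_bad("haugh must be finite")
  wl <- gen_wavelengths(config)
  fr <- mode_fractions(mode, config)
  v <- fr[["alpha"]] * s_interior(wl, haugh, config) +
    (1 - fr[["alpha"]] - fr[["beta"]]) * s_shell(wl, config) +
    fr[["beta"]] * s_source(wl, config)
  b <- stats::rnorm(1L, 1, config$multiplicative_sd)
  a <- stats::rnorm(1L, 0, config$additive_sd)
  v <- v * b + a + stats::rnorm(length(wl), 0, config$channel_noise_sd)
  n_clip <- sum(v < 0)
  v[v < 0] <- 0
  structure(list(wavelengths_nm = wl, values = v),
            class = "spectrum", n_clipped = n_clip)
}

# Noise-free mixture (used by scene rendering and by tests as ground truth).
egg_spectrum_clean <- function(haugh, mode, config = generator_config()) {
  wl <- gen_wavelengths(config)
  fr <- mode_fractions(mode, config)
  v <- fr[["alpha"]] * s_interior(wl, haugh, config) +
    (1 - fr[["alpha"]] - fr[["beta"]]) * s_shell(wl, config) +
    fr[["beta"]] * s_source(wl, config)
  structure(list(wavelengths_nm = wl, values = v), class = "spectrum")
}

# ---- cohorts ---------------------------------------------------------------

#' Simulate a storage cohort of eggs
#'
#' Draws `eggs_per_day` eggs on each of `n_days` storage days. Each egg gets a
#' weight uniform on the configured range, a Haugh unit from the linear
#' degradation law plus Gaussian biological noise, a protein height
#' back-solved from the Haugh formula (so the formula round-trips exactly), a
#' week-based grade, and one spectrum per requested acquisition mode.
#'
#' @param n_days number of storage days (1-28; grading is undefined beyond
#'   four weeks).
#' @param eggs_per_day eggs measured per day.
#' @param modes list of [acquisition_mode()] objects (may be empty for a
#'   spectra-free cohort); defaults to all nine.
#' @param config a [generator_config()]; its `seed` fixes all randomness.
#' @return Object of class `egg_cohort`: a `records` data frame (egg_id, day,
#'   weight_g, protein_height_mm, haugh, grade) plus one spectra matrix per
#'   mode, the wavelength axis, and the config.
#' @examples
#' coh <- simulate_cohort(28, 2, modes = list(acquisition_mode("scatter", 0)),
#'                        config = generator_config(n_bands = 32, seed = 7))
#' table(coh$records$grade)
#' @export
simulate_cohort <- function(n_days, eggs_per_day, modes = all_modes(),
                            config = generator_config()) {
  n_days <- as.integer(n_days)
  eggs_per_day <- as.integer(eggs_per_day)
  if (n_days < 1L || eggs_per_day < 1L) stop_bad("n_days and eggs_per_day must be >= 1")
  if (n_days > 28L) {
    stop_bad("n_days > 28: the grading table covers four weeks only")
  }
  if (length(modes) && !all(vapply(modes, inherits, logical(1), "acq_mode"))) {
    stop_bad("modes must be acquisition_mode objects")
  }
  labels <- vapply(modes, mode_label, character(1))
  if (anyDuplicated(labels)) stop_bad("duplicate modes requested")
  n <- n_days * eggs_per_day
  wl <- gen_wavelengths(config)
  with_seed(config$seed, {
    day <- rep(seq_len(n_days), each = eggs_per_day)
    weight <- stats::runif(n, config$weight_range_g[1], config$weight_range_g[2])
    haugh <- config$intercept + config$slope_per_day * day +
      stats::rnorm(n, 0, config$haugh_noise_sd)
    height <- haugh_invert(haugh, weight)
    records <- data.frame(
      egg_id = sprintf("egg_d%02d_%02d", day, rep(seq_len(eggs_per_day), n_days)),
      day = day,
      weight_g = weight,
      protein_height_mm = height,
      haugh = haugh,
      grade = grade_of_day(day),
      stringsAsFactors = FALSE
    )
    spectra <- lapply(modes, function(m) {
      X <- matrix(0, n, config$n_bands)
      for (i in seq_len(n)) {
        X[i, ] <- egg_spectrum(haugh[i], m, config)$values
      }
      rownames(X) <- records$egg_id
      X
    })
    names(spectra) <- labels
    structure(
      list(records = records, spectra = spectra, wavelengths_nm = wl,
           modes = modes, config = config),
      class = "egg_cohort"
    )
  })
}

#' @export
print.egg_cohort <- function(x, ...) {
  cat(sprintf("<egg_cohort: %d eggs over %d day(s), %d mode(s), %d bands>\n",
              nrow(x$records), length(unique(x$records$day)),
              length(x$modes), length(x$wavelengths_nm)))
  print(table(grade = x$records$grade))
  invisible(x)
}

#' Spectra of a cohort under one mode
#'
#' @param cohort an [simulate_cohort()] result.
#' @param mode an [acquisition_mode()] or its label.
#' @return A [spectra_matrix()].
#' @export
cohort_spectra <- function(cohort, mode) {
  stopifnot(inherits(cohort, "egg_cohort"))
  label <- if (inherits(mode, "acq_mode")) mode_label(mode) else as.character(mode)
  X <- cohort$spectra[[label]]
  if (is.null(X)) stop_bad("cohort has no spectra for mode ", label)
  spectra_matrix(X, cohort$wavelengths_nm, cohort$records$egg_id)
}

#' Export a cohort as a long table
#'
#' One row per egg x mode: identity, day, weight, Haugh unit, grade, mode
#' label, then one column per band (headed `nm<wavelength>`). Suitable for
#' `write.csv`.
#'
#' @param x an `egg_cohort`.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.egg_cohort <- function(x, ...) {
  if (!length(x$modes)) {
    return(x$records)
  }
  out <- do.call(rbind, lapply(names(x$spectra), function(lbl) {
    df <- x$records[, c("egg_id", "day", "weight_g", "haugh")]
    df$grade <- as.character(x$records$grade)
    df$mode <- lbl
    cbind(df, stats::setNames(
      as.data.frame(x$spectra[[lbl]]),
      sprintf("nm%.1f", x$wavelengths_nm)))
  }))
  rownames(out) <- NULL
  out
}

# ---- scene rendering -------------------------------------------------------

#' Render a synthetic hyperspectral scene
#'
#' Places one elliptical egg per supplied spectrum on a dark background and
#' produces the raw cube together with matching all-white and all-dark
#' reference frames, emulating a line-scan acquisition: the raw pixel
#' intensity is `dark + gain(lambda) * signal`, where the signal is the
#' background spectrum or the egg spectrum scaled by Lambertian-style shading
#' in \[0.6, 1\], with a few specular glare pixels carrying the flat source
#' spectrum. Black/white correction ([black_white_correct()]) therefore
#' recovers `shading * spectrum` up to the channel noise.
#'
#' @param spectra list of spectra (as returned by [egg_spectrum()]), one per egg.
#' @param layout list of ellipses, each `list(center = c(row, col),
#'   axes = c(semi_row, semi_col))` in pixels (1-based).
#' @param image_size `c(rows, cols)`.
#' @param config a [generator_config()] (band axis and noise levels).
#' @param seed integer seed for glare placement and noise.
#' @return List with `raw`, `white`, `dark` hypercubes, `shading`
#'   (rows x cols matrix of the applied shading, 0 outside eggs), `owner`
#'   (egg index per pixel) and `glare` (linear pixel indices of the glare).
#' @export
render_scene <- function(spectra, layout, image_size, config = generator_config(),
                         seed = config$seed) {
  if (length(spectra) != length(layout)) {
    stop_bad("need exactly one layout ellipse per spectrum")
  }
  rows <- image_size[1L]; cols <- image_size[2L]
  wl <- gen_wavelengths(config)
  nb <- length(wl)
  for (sp in spectra) {
    if (length(sp$values) != nb) stop_bad("spectrum band count does not match config")
  }
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  owner <- matrix(0L, rows, cols)
  rho2 <- matrix(0, rows, cols)
  for (k in seq_along(layout)) {
    el <- layout[[k]]
    ctr <- el$center; ax <- el$axes
    if (ctr[1] - ax[1] < 1 || ctr[1] + ax[1] > rows ||
        ctr[2] - ax[2] < 1 || ctr[2] + ax[2] > cols) {
      stop_bad("ellipse ", k, " extends outside the image bounds")
    }
    d2 <- ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2
    inside <- d2 <= 1
    if (any(owner[inside] != 0L)) stop_bad("ellipses ", unique(owner[inside][owner[inside] != 0]),
                                           " and ", k, " overlap")
    owner[inside] <- k
    rho2[inside] <- d2[inside]
  }
  t <- (wl - config$wavelength_min_nm) /
    (config$wavelength_max_nm - config$wavelength_min_nm)
  gain <- 0.7 + 0.5 * t
  dark_level <- 0.04
  bg_spec <- 0.12 + 0.02 * t
  src_spec <- rep(1.3, nb)    # specular glare: above white, survives correction > 1
  shading <- matrix(0, rows, cols)
  shading[owner > 0] <- 1 - 0.4 * rho2[owner > 0]
  with_seed(seed, {
    signal <- array(0, c(rows, cols, nb))
    for (b in seq_len(nb)) signal[, , b] <- bg_spec[b]
    glare_all <- integer(0)
    for (k in seq_along(spectra)) {
      idx <- which(owner == k)
      for (b in seq_len(nb)) {
        plane <- signal[, , b]
        plane[idx] <- spectra[[k]]$values[b] * shading[idx]
        signal[, , b] <- plane
      }
      n_glare <- max(1L, round(0.01 * length(idx)))
      glare <- idx[sample_int(length(idx), min(n_glare, length(idx)))]
      glare_all <- c(glare_all, glare)
      for (b in seq_len(nb)) {
        plane <- signal[, , b]
        plane[glare] <- src_spec[b]
        signal[, , b] <- plane
      }
    }
    noise <- array(stats::rnorm(rows * cols * nb, 0, config$channel_noise_sd),
                   c(rows, cols, nb))
    raw <- array(dark_level, c(rows, cols, nb))
    white <- array(dark_level, c(rows, cols, nb))
    for (b in seq_len(nb)) {
      raw[, , b] <- dark_level + gain[b] * (signal[, , b] + noise[, , b])
      white[, , b] <- dark_level + gain[b]
    }
    dark <- array(dark_level + stats::rnorm(rows * cols * nb, 0, 5e-4),
                  c(rows, cols, nb))
    list(
      raw = hypercube(raw, wl),
      white = hypercube(white, wl),
      dark = hypercube(dark, wl),
      shading = shading,
      owner = owner,
      glare = glare_all
    )
  })
}

# Fisher ratio of a labelled spectra matrix: between-class over within-class
# variance, summed over bands. Used to quantify how much grade information a
# mode's spectra carry.
fisher_ratio <- function(X, labels) {
  labels <- as.factor(labels)
  overall <- colMeans(X)
  between <- 0; within <- 0
  for (g in levels(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    mu <- colMeans(Xi)
    between <- between + nrow(Xi) * (mu - overall)^2
    within <- within + colSums(sweep(Xi, 2, mu)^2)
  }
  sum(between / pmax(within, .Machine$double.eps))
}
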