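#' Spectral preprocessor specification
#'
#' One of the ten preprocessing methods, identified exactly as in the study's
#' result tables:
#' * row-wise (no training state): `"msc"` multiplicative scatter correction
#'   (needs a fitted reference), `"snv"` standard normal variate, `"norm"`
#'   per-row min-max normalization, `"ma"` moving average, `"detrend"`
#'   order-2 polynomial baseline removal, `"sg"`, `"sg-fd"`, `"sg-sd"`
#'   Savitzky-Golay smoothing / first / second derivative;
#' * column-wise (training state required): `"mc"` mean centering, `"auto"`
#'   autoscaling.
#'
#' Methods with training state (`msc`, `mc`, `auto`) must be fitted with
#' [pp_fit()] before [pp_transform()]; this is what keeps test-set statistics
#' out of the pipeline (no leakage).
#'
#' @param method method identifier (see above).
#' @param window odd window width for `ma` and the SG family (defaults 5 and
#'   11 respectively).
#' @param polyorder polynomial order for the SG family and `detrend`
#'   (default 2); must be below `window` for SG.
#' @return Object of class `preprocessor`.
#' @examples
#' p <- pp_fit(preprocessor("auto"), spectra_matrix(matrix(rnorm(40), 10), 1:4))
#' @export
preprocessor <- function(method = c("msc", "snv", "norm", "auto", "mc", "ma",
                                    "detrend", "sg", "sg-fd", "sg-sd"),
                         window = NULL, polyorder = 2L) {
  method <- match.arg(method)
  deriv <- switch(method, `sg-fd` = 1L, `sg-sd` = 2L, 0L)
  if (method %in% c("sg", "sg-fd", "sg-sd")) {
    window <- as.integer(window %||% 11L)
    if (window %% 2L == 0L || window <= polyorder) {
      stop_bad("SG window must be odd and greater than polyorder")
    }
    if (polyorder < deriv) stop_bad("SG polyorder must be >= derivative order")
  } else if (method == "ma") {
    window <- as.integer(window %||% 5L)
    if (window %% 2L == 0L || window < 1L) stop_bad("MA window must be odd and >= 1")
  } else {
    window <- NULL
  }
  structure(list(method = method, window = window,
                 polyorder = as.integer(polyorder), deriv = deriv,
                 fitted_state = NULL),
            class = "preprocessor")
}

#' @export
print.preprocessor <- function(x, ...) {
  cat(sprintf("<preprocessor: %s%s%s>\n", x$method,
              if (!is.null(x$window)) paste0(", window ", x$window) else "",
              if (is.null(x$fitted_state)) "" else ", fitted"))
  invisible(x)
}

#' Fit a preprocessor on training spectra
#'
#' Stores whatever training statistics the method needs: the training mean
#' spectrum for MSC, column means (and sds) for mean centering and
#' autoscaling. Row-wise methods store nothing but remember the band axis so
#' that transforms are checked against it.
#'
#' @param prep a [preprocessor()].
#' @param train a [spectra_matrix()] (>= 2 rows for methods with state).
#' @return The fitted preprocessor.
#' @export
pp_fit <- function(prep, train) {
  stopifnot(inherits(prep, "preprocessor"))
  train <- as_spectra(train)
  state <- list(wavelengths_nm = train$wavelengths_nm)
  if (prep$method %in% c("msc", "mc", "auto") && nrow(train$X) < 2L) {
    stop_bad(prep$method, " needs at least 2 training spectra")
  }
  if (prep$method == "msc") {
    state$reference <- colMeans(train$X)
  } else if (prep$method %in% c("mc", "auto")) {
    state$means <- colMeans(train$X)
    if (prep$method == "auto") {
      sds <- apply(train$X, 2, stats::sd)
      zero <- which(sds == 0)
      if (length(zero)) {
        stop_bad("autoscale: zero column sd at band ",
                 format(train$wavelengths_nm[zero[1L]]), " nm (column ", zero[1L], ")")
      }
      state$sds <- sds
    }
  }
  prep$fitted_state <- state
  prep
}

#' Apply a fitted preprocessor
#'
#' @param prep a (fitted, where the method requires it) [preprocessor()].
#' @param spectra a [spectra_matrix()] on the same band axis as the fit.
#' @return A [spectra_matrix()]; the SG family shrinks the band axis to the
#'   valid interior points (no edge padding is invented).
#' @export
pp_transform <- function(prep, spectra) {
  stopifnot(inherits(prep, "preprocessor"))
  spectra <- as_spectra(spectra)
  X <- spectra$X
  wl <- spectra$wavelengths_nm
  if (!is.null(prep$fitted_state) &&
      !isTRUE(all.equal(prep$fitted_state$wavelengths_nm, wl))) {
    stop_bad("band axis does not match the axis the preprocessor was fitted on")
  }
  if (prep$method %in% c("msc", "mc", "auto") && is.null(prep$fitted_state)) {
    stop_bad(prep$method, " must be fitted with pp_fit() before transforming")
  }
  out <- switch(prep$method,
    snv = {
      mu <- rowMeans(X)
      sds <- apply(X, 1, stats::sd)
      if (any(sds == 0)) stop_bad("SNV undefined for zero-variance row ",
                                  which(sds == 0)[1L])
      (X - mu) / sds
    },
    msc = {
      ref <- prep$fitted_state$reference
      refc <- ref - mean(ref)
      denom <- sum(refc^2)
      t(apply(X, 1, function(x) {
        b <- sum((x - mean(x)) * refc) / denom
        if (abs(b) < 1e-12) stop_bad("MSC regression slope is zero for a row")
        a <- mean(x) - b * mean(ref)
        (x - a) / b
      }))
    },
    norm = {
      rng <- t(apply(X, 1, range))
      span <- rng[, 2] - rng[, 1]
      if (any(span == 0)) stop_bad("min-max normalization undefined for constant row ",
                                   which(span == 0)[1L])
      (X - rng[, 1]) / span
    },
    mc = sweep(X, 2, prep$fitted_state$means),
    auto = sweep(sweep(X, 2, prep$fitted_state$means), 2,
                 prep$fitted_state$sds, "/"),
    ma = moving_average(X, prep$window),
    detrend = detrend_rows(X, wl, prep$polyorder),
    `sg` = , `sg-fd` = , `sg-sd` = {
      return(sg_transform(spectra, prep))
    }
  )
  spectra_matrix(out, wl, spectra$sample_ids)
}

# Centered moving average with edge-truncated windows (output keeps all bands).
moving_average <- function(X, window) {
  h <- (window - 1L) %/% 2L
  p <- ncol(X)
  cs <- cbind(0, t(apply(X, 1, cumsum)))
  lo <- pmax(1L, seq_len(p) - h)
  hi <- pmin(p, seq_len(p) + h)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(X))
}

# Remove a per-row least-squares polynomial baseline in wavelength.
detrend_rows <- function(X, wl, order) {
  A <- stats::poly(wl, degree = order, raw = FALSE)
  A <- cbind(1, A)
  H <- A %*% solve(crossprod(A), t(A))
  X - X %*% t(H)
}

# Savitzky-Golay convolution weights for one output point: local least-squares
# polynomial fit on an index window, derivative d evaluated at the center.
sg_coefficients <- function(window, polyorder, deriv) {
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:polyorder, `^`)
  G <- solve(crossprod(A), t(A))
  G[deriv + 1L, ] * factorial(deriv)
}

# Shrink-to-valid SG transform: output bands are the interior points where the
# full window fits; derivatives are scaled by the (uniform) band spacing.
sg_transform <- function(spectra, prep) {
  X <- spectra$X; wl <- spectra$wavelengths_nm
  w <- prep$window; h <- (w - 1L) %/% 2L
  p <- ncol(X)
  if (p < w) stop_bad("SG window wider than the band axis")
  cf <- sg_coefficients(w, prep$polyorder, prep$deriv)
  dl <- mean(diff(wl))
  # convolution as a banded matrix multiply: out[, j] = X[, j:(j+w-1)] %*% cf
  n_out <- p - w + 1L
  W <- matrix(0, p, n_out)
  for (j in seq_len(n_out)) W[j:(j + w - 1L), j] <- cf
  out <- (X %*% W) / dl^prep$deriv
  spectra_matrix(out, wl[(h + 1L):(p - h)], spectra$sample_ids)
}
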