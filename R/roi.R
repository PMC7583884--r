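#' Pseudo-RGB rendering of a cube
#'
#' Extracts the bands nearest to the requested red/green/blue wavelengths
#' (defaults 650/550/450 nm, the usual visualization choice) as a rows x
#' cols x 3 array. Ties between two equally near bands resolve to the lower
#' wavelength.
#'
#' @param cube a [hypercube()].
#' @param r_nm,g_nm,b_nm requested channel wavelengths, nm; must lie within
#'   the cube's wavelength range.
#' @return Numeric array `[lines, samples, 3]`.
#' @export
pseudo_rgb <- function(cube, r_nm = 650, g_nm = 550, b_nm = 450) {
  stopifnot(inherits(cube, "hypercube"))
  idx <- vapply(c(r_nm, g_nm, b_nm), nearest_band, integer(1),
                wavelengths = cube$wavelengths_nm)
  out <- cube$data[, , idx, drop = FALSE]
  dimnames(out) <- NULL
  out
}

# Nearest band to a requested wavelength; ties -> lower wavelength; errors
# outside the axis range.
nearest_band <- function(request, wavelengths) {
  if (request < min(wavelengths) || request > max(wavelengths)) {
    stop_bad(sprintf("requested wavelength %.1f nm outside axis range %.1f-%.1f nm",
                     request, min(wavelengths), max(wavelengths)))
  }
  d <- abs(wavelengths - request)
  cand <- which(d == min(d))
  cand[which.min(wavelengths[cand])]
}

#' Mask extraction parameters
#'
#' @param threshold `"otsu"` for automatic global thresholding, or a numeric
#'   fixed threshold on the grayscale image.
#' @param morph_radius_px disk radius of the closing (dilation then erosion).
#' @param expand_factor ellipse inflation factor in \[1, 1.5\]; the fitted
#'   ellipse is slightly expanded so that the ROI covers the whole egg.
#' @param min_area_px connected components smaller than this are discarded.
#' @return Object of class `mask_params`.
#' @export
mask_params <- function(threshold = "otsu", morph_radius_px = 2L,
                        expand_factor = 1.05, min_area_px = 50L) {
  if (!(identical(threshold, "otsu") || is.numeric(threshold))) {
    stop_bad("threshold must be 'otsu' or a number")
  }
  if (morph_radius_px < 0) stop_bad("morph_radius_px must be >= 0")
  if (expand_factor < 1 || expand_factor > 1.5) {
    stop_bad("expand_factor must lie in [1, 1.5]")
  }
  structure(list(threshold = threshold,
                 morph_radius_px = as.integer(morph_radius_px),
                 expand_factor = expand_factor,
                 min_area_px = as.integer(min_area_px)),
            class = "mask_params")
}

#' Extract elliptical egg ROIs from an image
#'
#' Implements the two-step automatic ROI extraction: the (pseudo-RGB or
#' grayscale) image is binarized (Otsu by default), closed with a disk
#' (dilation then erosion), labelled into 8-connected components ("cell
#' counting"), small components are discarded, and each surviving component
#' is replaced by an ellipse centered at its centroid with semi-axes equal to
#' half its maximum horizontal/vertical extents times `expand_factor`.
#' Components are numbered in raster order of their centroids.
#'
#' @param image rows x cols matrix, or rows x cols x 3 pseudo-RGB array
#'   (averaged to grayscale).
#' @param params a [mask_params()].
#' @return Object of class `roi_mask`: `labels` (integer matrix, 0 =
#'   background), `ellipses` (per label: `center`, `semi_axes`, both
#'   (row, col)), and `params`. An image with no surviving component yields an
#'   all-zero mask with a warning.
#' @export
egg_mask <- function(image, params = mask_params()) {
  stopifnot(inherits(params, "mask_params"))
  gray <- if (length(dim(image)) == 3L) {
    apply(image, c(1, 2), mean)
  } else {
    as.matrix(image)
  }
  if (any(!is.finite(gray))) stop_bad("image must be finite")
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(gray) else params$threshold
  bin <- gray > thr
  if (params$morph_radius_px > 0) {
    bin <- erode_bin(dilate_bin(bin, params$morph_radius_px), params$morph_radius_px)
  }
  comp <- label_components(bin)
  sizes <- tabulate(comp[comp > 0L])
  keep <- which(sizes >= params$min_area_px)
  if (!length(keep)) {
    warning("no component survives thresholding/min_area; returning empty mask")
    return(structure(list(labels = matrix(0L, nrow(gray), ncol(gray)),
                          ellipses = list(), params = params),
                     class = "roi_mask"))
  }
  info <- lapply(keep, function(k) {
    idx <- which(comp == k, arr.ind = TRUE)
    center <- c(mean(idx[, 1]), mean(idx[, 2]))
    # max horizontal extent: widest row; max vertical extent: tallest column
    h_ext <- max(tapply(idx[, 2], idx[, 1], function(v) diff(range(v)) + 1))
    v_ext <- max(tapply(idx[, 1], idx[, 2], function(v) diff(range(v)) + 1))
    list(center = center,
         semi_axes = c(v_ext / 2, h_ext / 2) * params$expand_factor)
  })
  ord <- order(vapply(info, function(e) e$center[1], numeric(1)),
               vapply(info, function(e) e$center[2], numeric(1)))
  info <- info[ord]
  labels <- matrix(0L, nrow(gray), ncol(gray))
  rr <- matrix(seq_len(nrow(gray)), nrow(gray), ncol(gray))
  cc <- matrix(seq_len(ncol(gray)), nrow(gray), ncol(gray), byrow = TRUE)
  for (k in seq_along(info)) {
    el <- info[[k]]
    inside <- ((rr - el$center[1]) / el$semi_axes[1])^2 +
      ((cc - el$center[2]) / el$semi_axes[2])^2 <= 1
    labels[inside & labels == 0L] <- k
  }
  structure(list(labels = labels, ellipses = info, params = params),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask: %d egg(s) in a %d x %d image>\n",
              length(x$ellipses), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Mean spectrum of each ROI
#'
#' The unweighted per-band mean over the pixels of each labelled ellipse; the
#' average spectrum of a single ROI is used as the spectrum of that egg.
#'
#' @param cube a [hypercube()] whose spatial shape matches the mask.
#' @param mask an [egg_mask()] result.
#' @return A [spectra_matrix()] with one row per label, ordered by label.
#' @export
roi_mean_spectra <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "roi_mask"))
  d <- dim(cube$data)
  if (!identical(d[1:2], dim(mask$labels))) {
    stop_bad("mask spatial shape does not match cube")
  }
  n_lab <- length(mask$ellipses)
  if (n_lab == 0L) stop_bad("mask has no labels")
  X <- matrix(0, n_lab, d[3L])
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  for (k in seq_len(n_lab)) {
    idx <- which(mask$labels == k)
    if (!length(idx)) stop_bad("label ", k, " has zero pixels")
    X[k, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  spectra_matrix(X, cube$wavelengths_nm, sample_ids = as.character(seq_len(n_lab)))
}

# ---- image primitives ------------------------------------------------------

# Otsu's global threshold: maximize between-class variance over a 256-bin
# histogram of the (range-normalized) image.
otsu_threshold <- function(gray) {
  rng <- range(gray)
  if (diff(rng) == 0) return(rng[1])
  x <- (gray - rng[1]) / diff(rng)
  breaks <- seq(0, 1, length.out = 257L)
  h <- tabulate(pmin(256L, findInterval(x, breaks, rightmost.closed = TRUE)), 256L)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + mids[k] * diff(rng)
}

disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

shift_mat <- function(m, dr, dc, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  r_src <- max(1, 1 - dr):min(nrow(m), nrow(m) - dr)
  c_src <- max(1, 1 - dc):min(ncol(m), ncol(m) - dc)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

dilate_bin <- function(bin, radius) {
  off <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(bin), ncol(bin))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(bin, off$dr[i], off$dc[i], FALSE)
  }
  out
}

erode_bin <- function(bin, radius) {
  off <- disk_offsets(radius)
  out <- matrix(TRUE, nrow(bin), ncol(bin))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mat(bin, off$dr[i], off$dc[i], FALSE)
  }
  out
}

# 8-connected component labelling by iterative flood fill.
label_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  labels <- matrix(0L, nr, nc)
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  cur <- 0L
  todo <- which(bin)
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((px - 1L) %% nr) + 1L
      c <- ((px - 1L) %/% nr) + 1L
      for (i in seq_len(nrow(nbr))) {
        r2 <- r + nbr$dr[i]; c2 <- c + nbr$dc[i]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          px2 <- (c2 - 1L) * nr + r2
          if (bin[px2] && labels[px2] == 0L) {
            labels[px2] <- cur
            stack <- c(stack, px2)
          }
        }
      }
    }
  }
  labels
}
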