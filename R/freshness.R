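#' Haugh unit of an egg
#'
#' The Haugh unit is the standard freshness index of a table egg, computed
#' from the average thick-albumen (protein) height `h` and the egg weight `w`:
#' \deqn{HU = 100 \log_{10}(h + 7.57 - 1.7\, w^{0.37})}
#' Fresh eggs score in the 80s; the score declines as the albumen thins with
#' storage time. Vectorized over `h` and `w`.
#'
#' @param h protein (thick albumen) height in mm, positive.
#' @param w egg weight in grams, non-negative.
#' @return Haugh units (dimensionless).
#' @seealso [haugh_invert()] for the inverse in `h`, [grade_of_day()] for the
#'   week-based grade labels.
#' @examples
#' haugh_unit(h = 2.43, w = 0)   # log argument exactly 10 -> 100
#' haugh_unit(h = 6, w = 60)
#' @export
haugh_unit <- function(h, w) {
  if (any(!is.finite(h)) || any(!is.finite(w))) stop_bad("h and w must be finite")
  if (any(h <= 0)) stop_bad("protein height h must be positive")
  if (any(w < 0)) stop_bad("weight w must be non-negative")
  arg <- h + 7.57 - 1.7 * w^0.37
  if (any(arg <= 0)) {
    stop_bad("Haugh unit undefined: h + 7.57 - 1.7*w^0.37 <= 0")
  }
  100 * log10(arg)
}

#' Protein height implied by a Haugh unit
#'
#' Solves the Haugh formula for the albumen height `h` at a given weight, so
#' that `haugh_unit(haugh_invert(HU, w), w) == HU`.
#'
#' @param hu Haugh units.
#' @param w egg weight in grams.
#' @return Protein height in mm.
#' @export
haugh_invert <- function(hu, w) {
  if (any(w < 0)) stop_bad("weight w must be non-negative")
  h <- 10^(hu / 100) - 7.57 + 1.7 * w^0.37
  if (any(h <= 0)) stop_bad("no positive protein height corresponds to this (HU, w)")
  h
}

#' Freshness grade levels
#'
#' Grades in descending freshness order: AA (week 1), A (week 2), B1 (week 3),
#' B2 (week 4). Eggs older than four weeks (spoiled, "grade C") are outside
#' the scope of the grading table.
#'
#' @return Character vector of the four grade labels.
#' @export
grade_levels <- function() c("AA", "A", "B1", "B2")

#' Grade implied by storage day
#'
#' Ground-truth grading maps the storage week to the grade: days 1-7 are AA,
#' 8-14 A, 15-21 B1, 22-28 B2.
#'
#' @param day integer storage day(s), 1 to 28.
#' @return Factor with levels `AA > A > B1 > B2`.
#' @examples
#' grade_of_day(c(1, 14, 15, 28))
#' @export
grade_of_day <- function(day) {
  if (any(day != as.integer(day))) stop_bad("day must be integer")
  day <- as.integer(day)
  if (any(day < 1L)) stop_bad("day must be >= 1")
  if (any(day > 28L)) {
    stop_bad("day > 28: grading is defined for four weeks only (older eggs spoil)")
  }
  factor(grade_levels()[ceiling(day / 7)], levels = grade_levels())
}

#' Fit the linear Haugh-unit degradation law
#'
#' Ordinary least squares of Haugh unit on storage day. Stored eggs lose
#' albumen quality at a nearly constant rate, so HU declines linearly with
#' time; the fitted slope is in units/day.
#'
#' @param days integer vector of storage days.
#' @param hu Haugh units, same length.
#' @return An object of class `degradation_fit` with components `slope`,
#'   `intercept`, `residual_sd` (from n - 2 degrees of freedom) and `n`.
#' @examples
#' d <- rep(1:28, each = 5)
#' fit_degradation(d, 85.70 - 1.75 * d + rnorm(length(d), sd = 4))
#' @export
fit_degradation <- function(days, hu) {
  if (length(days) != length(hu)) stop_bad("days and hu must have equal length")
  if (length(days) < 2L) stop_bad("need at least 2 points")
  if (length(unique(days)) < 2L) stop_bad("need at least 2 distinct days")
  fit <- stats::lm(hu ~ days, data = data.frame(days = days, hu = hu))
  cf <- stats::coef(fit)
  n <- length(days)
  rsd <- if (n > 2L) sqrt(sum(stats::residuals(fit)^2) / (n - 2L)) else 0
  structure(
    list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
         residual_sd = rsd, n = n),
    class = "degradation_fit"
  )
}

#' @export
print.degradation_fit <- function(x, digits = 4, ...) {
  cat("Linear Haugh-unit degradation fit (n =", x$n, "eggs)\n")
  cat(sprintf("  HU = %.*f %+.*f * day   (residual sd %.*f)\n",
              digits, x$intercept, digits, x$slope, digits, x$residual_sd))
  invisible(x)
}

#' @export
coef.degradation_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.degradation_fit <- function(object, newdata, ...) {
  days <- if (is.data.frame(newdata)) newdata$days else newdata
  object$intercept + object$slope * days
}
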