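#' Acquisition modes
#'
#' An acquisition mode describes the illumination geometry of a hyperspectral
#' measurement: dome-illuminated `reflection`, `transmission` through the egg,
#' or fiber-optic `scatter` at an incident angle between 0 and 60 degrees
#' (0 degrees is pure scattering; 10-60 degrees mix scattered and
#' surface-reflected light). Nine distinct modes exist in total.
#'
#' @param kind one of `"reflection"`, `"transmission"`, `"scatter"`.
#' @param angle_deg incident angle in degrees, one of 0, 10, ..., 60;
#'   required (and only allowed) when `kind = "scatter"`.
#' @return An object of class `acq_mode` with fields `kind` and `angle_deg`.
#' @examples
#' acquisition_mode("scatter", 0)
#' acquisition_mode("reflection")
#' @export
acquisition_mode <- function(kind = c("reflection", "transmission", "scatter"),
                             angle_deg = NULL) {
  kind <- match.arg(kind)
  if (kind == "scatter") {
    if (is.null(angle_deg) || !angle_deg %in% seq(0L, 60L, by = 10L)) {
      stop_bad("scatter mode requires angle_deg in {0, 10, 20, 30, 40, 50, 60}")
    }
    angle_deg <- as.integer(angle_deg)
  } else if (!is.null(angle_deg)) {
    stop_bad("angle_deg is defined only for kind = 'scatter'")
  }
  structure(list(kind = kind, angle_deg = angle_deg), class = "acq_mode")
}

#' All nine acquisition modes
#'
#' Dome reflection, transmission, and the seven fiber-optic scattering angles.
#'
#' @return A named list of [acquisition_mode()] objects.
#' @export
all_modes <- function() {
  m <- c(
    list(acquisition_mode("reflection"), acquisition_mode("transmission")),
    lapply(seq(0L, 60L, by = 10L), function(a) acquisition_mode("scatter", a))
  )
  names(m) <- vapply(m, mode_label, character(1))
  m
}

#' Label of an acquisition mode
#'
#' @param mode an [acquisition_mode()].
#' @return A string such as `"reflection"` or `"scatter_20"`.
#' @export
mode_label <- function(mode) {
  stopifnot(inherits(mode, "acq_mode"))
  if (mode$kind == "scatter") paste0("scatter_", mode$angle_deg) else mode$kind
}

#' @export
print.acq_mode <- function(x, ...) {
  cat("<acquisition mode:", mode_label(x), ">\n")
  invisible(x)
}

# Parse "scatter_40" / "reflection" back into a mode object.
parse_mode <- function(label) {
  if (label %in% c("reflection", "transmission")) {
    return(acquisition_mode(label))
  }
  if (grepl("^scatter_[0-9]+$", label)) {
    return(acquisition_mode("scatter", as.integer(sub("^scatter_", "", label))))
  }
  stop_bad("unknown mode label: ", label)
}
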