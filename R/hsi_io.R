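#' Hyperspectral cube
#'
#' A three-dimensional reflectance (or raw-intensity) array with dimensions
#' lines x samples x bands and a wavelength axis. `interleave` records the
#' on-disk band ordering used by [write_envi()]; in memory the array is always
#' stored `[line, sample, band]`.
#'
#' @param data numeric 3-d array, lines x samples x bands.
#' @param wavelengths_nm numeric vector, one entry per band.
#' @param interleave file interleave, `"BSQ"`, `"BIL"` or `"BIP"`.
#' @param mode optional [acquisition_mode()] metadata.
#' @return Object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths_nm, interleave = c("BSQ", "BIL", "BIP"),
                      mode = NULL) {
  interleave <- match.arg(interleave)
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop_bad("data must be a 3-d array")
  if (any(dim(data) < 1L)) stop_bad("all cube dimensions must be >= 1")
  if (dim(data)[3L] != length(wavelengths_nm)) {
    stop_bad("bands (", dim(data)[3L], ") != wavelength count (",
             length(wavelengths_nm), ")")
  }
  if (!is.null(mode)) stopifnot(inherits(mode, "acq_mode"))
  storage.mode(data) <- "double"
  structure(
    list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
         interleave = interleave, mode = mode),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube: %d lines x %d samples x %d bands (%s)%s>\n",
              d[1], d[2], d[3], x$interleave,
              if (is.null(x$mode)) "" else paste0(", mode ", mode_label(x$mode))))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Black/white reflectance correction
#'
#' Converts a raw hyperspectral cube to relative reflectance using a white
#' reference frame (total-reflection PTFE plate) and a dark frame (lens
#' capped), correcting for dark current and uneven illumination:
#' \deqn{R = (I_0 - I_b) / (I_w - I_b)}
#' applied elementwise. The result is deliberately not clipped to \[0, 1\]
#' (specular glare can exceed 1 physically).
#'
#' @param raw original cube \eqn{I_0}.
#' @param white white-reference cube \eqn{I_w}, same shape and wavelengths.
#' @param dark dark cube \eqn{I_b}, same shape and wavelengths.
#' @return A `hypercube` of reflectances with the wavelength axis preserved.
#' @examples
#' wl <- c(500, 600)
#' cube <- function(v) hypercube(array(v, c(2, 2, 2)), wl)
#' black_white_correct(cube(0.6), cube(1), cube(0.2))  # 0.5 everywhere
#' @export
black_white_correct <- function(raw, white, dark) {
  for (f in list(raw, white, dark)) stopifnot(inherits(f, "hypercube"))
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(dark$data))) {
    stop_bad("raw, white and dark cubes must share one shape")
  }
  if (!isTRUE(all.equal(raw$wavelengths_nm, white$wavelengths_nm)) ||
      !isTRUE(all.equal(raw$wavelengths_nm, dark$wavelengths_nm))) {
    stop_bad("raw, white and dark cubes must share one wavelength axis")
  }
  denom <- white$data - dark$data
  bad <- which(denom == 0)
  if (length(bad)) {
    ix <- arrayInd(bad[1L], dim(denom))
    stop_bad(sprintf(
      "white and dark frames coincide at %d pixel/band cell(s); first at line %d, sample %d, band %d",
      length(bad), ix[1], ix[2], ix[3]))
  }
  hypercube((raw$data - dark$data) / denom, raw$wavelengths_nm,
            interleave = raw$interleave, mode = raw$mode)
}

# ---- ENVI-dialect reader/writer --------------------------------------------

# data type codes of the ENVI core set that we support
.envi_types <- list(
  `4` = list(what = "numeric", size = 4L),
  `5` = list(what = "numeric", size = 8L)
)

#' Write a hypercube in ENVI format
#'
#' Writes a binary data file at `path` plus a text header `path.hdr` using the
#' common ENVI core keys (samples, lines, bands, data type, interleave, byte
#' order, wavelength). Doubles (data type 5) are the default so that round
#' trips are value-exact.
#'
#' @param cube a [hypercube()].
#' @param path data-file path; the header is written to `paste0(path, ".hdr")`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @seealso [read_envi()]
#' @export
write_envi <- function(cube, path, data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  data_type <- as.integer(data_type)
  tp <- .envi_types[[as.character(data_type)]]
  if (is.null(tp)) stop_bad("unsupported ENVI data type: ", data_type)
  d <- dim(cube$data)
  # in-memory layout is [line, sample, band]; file layouts (fastest axis first):
  #   BSQ: sample, line, band ; BIL: sample, band, line ; BIP: band, sample, line
  perm <- switch(cube$interleave,
    BSQ = c(2L, 1L, 3L),
    BIL = c(2L, 3L, 1L),
    BIP = c(3L, 2L, 1L)
  )
  vec <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(vec, con, size = tp$size, endian = "little")
  hdr <- c(
    "ENVI",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", tolower(cube$interleave)),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(cube$wavelengths_nm, digits = 15, trim = TRUE),
                                   collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read a hypercube from ENVI format
#'
#' @param path data-file path written by [write_envi()] (or any ENVI pair with
#'   the core header keys); the header is looked for at `paste0(path, ".hdr")`.
#' @return A [hypercube()].
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(path)) stop_bad("ENVI data file not found: ", path)
  if (!file.exists(hdr_path)) stop_bad("ENVI header not found: ", hdr_path)
  hdr <- .parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop_bad("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  samples <- as.integer(hdr[["samples"]])
  lines <- as.integer(hdr[["lines"]])
  bands <- as.integer(hdr[["bands"]])
  data_type <- as.integer(hdr[["data type"]])
  interleave <- toupper(hdr[["interleave"]])
  if (!interleave %in% c("BSQ", "BIL", "BIP")) {
    stop_bad("unsupported interleave: ", interleave)
  }
  tp <- .envi_types[[as.character(data_type)]]
  if (is.null(tp)) stop_bad("unsupported ENVI data type: ", data_type)
  byte_order <- as.integer(hdr[["byte order"]] %||% "0")
  endian <- if (byte_order == 0L) "little" else "big"
  wl <- hdr[["wavelength"]]
  if (is.null(wl)) stop_bad("ENVI header missing field(s): wavelength")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1L]])
  if (length(wl) != bands) {
    stop_bad("header declares ", bands, " bands but ", length(wl), " wavelengths")
  }
  n <- samples * lines * bands
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vec <- readBin(con, what = tp$what, n = n, size = tp$size, endian = endian)
  if (length(vec) != n) stop_bad("ENVI data file shorter than header declares")
  dims <- switch(interleave,
    BSQ = c(samples, lines, bands),
    BIL = c(samples, bands, lines),
    BIP = c(bands, samples, lines)
  )
  inv <- switch(interleave,          # inverse of the write permutation
    BSQ = c(2L, 1L, 3L),
    BIL = c(3L, 1L, 2L),
    BIP = c(3L, 2L, 1L)
  )
  arr <- aperm(array(vec, dims), inv)
  hypercube(arr, wl, interleave = interleave)
}

.parse_envi_header <- function(hdr_path) {
  raw_lines <- readLines(hdr_path, warn = FALSE)
  # fold multi-line { ... } values onto one line
  lines <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in raw_lines) {
    if (!open) {
      buf <- ln
      open <- grepl("\\{", ln) && !grepl("\\}", ln)
    } else {
      buf <- paste(buf, ln)
      open <- !grepl("\\}", ln)
    }
    if (!open) lines <- c(lines, buf)
  }
  lines <- lines[grepl("=", lines)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), tolower(keys))
}
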