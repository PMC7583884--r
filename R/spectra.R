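#' Spectra matrix
#'
#' The tabular container used by preprocessing, wavelength selection and
#' classification: one row per sample, one column per wavelength.
#'
#' @param X numeric matrix, n_samples x n_bands; no NA/NaN allowed.
#' @param wavelengths_nm strictly increasing numeric vector, one per column.
#' @param sample_ids optional identifiers, recycled to row names.
#' @return Object of class `spectra_matrix` with fields `X`, `wavelengths_nm`,
#'   `sample_ids`.
#' @export
spectra_matrix <- function(X, wavelengths_nm, sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop_bad("spectra must be finite, no NA")
  if (ncol(X) != length(wavelengths_nm)) {
    stop_bad("column count (", ncol(X), ") != wavelength count (",
             length(wavelengths_nm), ")")
  }
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0)) {
    stop_bad("wavelengths must be strictly increasing")
  }
  if (is.null(sample_ids)) sample_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  structure(
    list(X = X, wavelengths_nm = as.numeric(wavelengths_nm),
         sample_ids = as.character(sample_ids)),
    class = "spectra_matrix"
  )
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix: %d samples x %d bands, %.1f-%.1f nm>\n",
              nrow(x$X), ncol(x$X),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$X)

#' @export
as.matrix.spectra_matrix <- function(x, ...) x$X

# Coerce a plain matrix (plus axis) or pass a spectra_matrix through.
as_spectra <- function(x, wavelengths_nm = NULL) {
  if (inherits(x, "spectra_matrix")) return(x)
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(ncol(as.matrix(x)))
  spectra_matrix(x, wavelengths_nm)
}
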