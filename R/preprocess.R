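# Spectral preprocessing: reflectance -> absorbance and Savitzky-Golay
# smoothing. No installed package provides SG filtering, so the
# least-squares convolution coefficients are derived here from the
# local polynomial fit they are defined by.

#' Convert reflectance spectra to absorbance
#'
#' Applies the Beer-Lambert conversion A(lambda) = log10(1 / R(lambda))
#' elementwise. The input must be in reflectance mode with all values in
#' (0, 1]; the output is the same set flagged as absorbance.
#'
#' @param s a [spectrum_set] in reflectance mode.
#' @return a [spectrum_set] in absorbance mode, same shape.
#' @export
reflectance_to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$mode != "reflectance") {
    stop("spectra are already in absorbance mode", call. = FALSE)
  }
  if (any(s$values <= 0)) {
    stop("reflectance <= 0 has no logarithm", call. = FALSE)
  }
  spectrum_set(-log10(s$values), s$wavelengths, mode = "absorbance",
               sample_ids = s$sample_ids, metadata = s$metadata)
}

#' Savitzky-Golay filter specification
#'
#' Describes a smoothing (derivative order 0) Savitzky-Golay filter:
#' a local least-squares polynomial of degree `poly_order` fitted over a
#' symmetric window of `2 * half_window + 1` points. The convolution
#' coefficients are obtained from the pseudoinverse of the local
#' Vandermonde design; for smoothing they always sum to 1.
#'
#' @param poly_order non-negative integer polynomial degree.
#' @param window odd window length `2m + 1`, strictly greater than
#'   `poly_order`.
#' @return an object of class `sg_filter` with fields `poly_order`,
#'   `half_window` and the coefficient vector `coefficients`.
#' @export
sg_filter <- function(poly_order = 2, window = 3) {
  stopifnot(length(poly_order) == 1, length(window) == 1)
  poly_order <- as.integer(poly_order)
  window <- as.integer(window)
  if (poly_order < 0) stop("poly_order must be non-negative", call. = FALSE)
  if (window < 3 || window %% 2 == 0) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (window <= poly_order) {
    stop("window length must exceed poly_order", call. = FALSE)
  }
  m <- (window - 1L) %/% 2L
  A <- outer(seq(-m, m), 0:poly_order, `^`)
  # fitted value at the window centre: first row of (A'A)^{-1} A'
  coef <- drop(solve(crossprod(A), t(A))[1L, ])
  structure(list(poly_order = poly_order, half_window = m, window = window,
                 coefficients = coef),
            class = "sg_filter")
}

#' @export
print.sg_filter <- function(x, ...) {
  cat(sprintf("<sg_filter> order %d, window %d (m = %d)\n",
              x$poly_order, x$window, x$half_window))
  invisible(x)
}

# Smooth a plain numeric matrix row-wise with mirror padding.
sg_smooth_matrix <- function(X, spec) {
  X <- check_finite_matrix(X)
  m <- spec$half_window
  p <- ncol(X)
  if (p < spec$window) {
    stop("window longer than spectrum", call. = FALSE)
  }
  # mirror about the end points without repeating them
  left <- X[, (m + 1L):2L, drop = FALSE]
  right <- X[, (p - 1L):(p - m), drop = FALSE]
  padded <- cbind(left, X, right)
  out <- matrix(0, nrow(X), p)
  for (j in seq_len(spec$window)) {
    out <- out + spec$coefficients[j] * padded[, (j - 1L) + seq_len(p),
                                               drop = FALSE]
  }
  dimnames(out) <- dimnames(X)
  out
}

#' Savitzky-Golay smoothing of spectra
#'
#' Convolves each spectrum with the least-squares polynomial smoothing
#' coefficients of `spec`. Edges are handled by mirror-padding
#' `half_window` points at each end, so the output has the same length
#' as the input and wavelength indices stay aligned across the
#' pipeline.
#'
#' Note that with the default order-2, window-3 filter the quadratic
#' interpolates its three points exactly, so smoothing is the identity;
#' a wider window (e.g. 7) is needed for the filter to do anything.
#'
#' @param s a [spectrum_set] or numeric matrix/vector.
#' @param spec an [sg_filter]; alternatively pass `poly_order` and
#'   `window`.
#' @param poly_order,window used to build the filter when `spec` is
#'   missing.
#' @return smoothed object of the same type as `s`.
#' @export
sg_smooth <- function(s, spec = NULL, poly_order = 2, window = 3) {
  if (is.null(spec)) spec <- sg_filter(poly_order, window)
  stopifnot(inherits(spec, "sg_filter"))
  if (inherits(s, "spectrum_set")) {
    out <- sg_smooth_matrix(s$values, spec)
    if (s$mode == "reflectance") {
      # smoothing can nudge values just past 1; clamp to the valid range
      out[out > 1] <- 1
      if (any(out <= 0)) {
        stop("smoothing produced non-positive reflectance", call. = FALSE)
      }
    }
    return(spectrum_set(out, s$wavelengths, mode = s$mode,
                        sample_ids = s$sample_ids, metadata = s$metadata))
  }
  if (is.null(dim(s))) {
    return(drop(sg_smooth_matrix(matrix(as.numeric(s), nrow = 1), spec)))
  }
  sg_smooth_matrix(s, spec)
}
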