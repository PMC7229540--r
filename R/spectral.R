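# Spectral core: DFT conventions, cross-power spectrum, correlation surface,
# wrapped integer peak localization.
#
# Conventions, fixed once and relied on by every other module:
#   * Forward transform: unnormalized, kernel exp(-2i*pi*(u*r/M1 + v*c/M2)),
#     frequencies in machine (unshifted) order -- exactly stats::fft().
#   * Cross-power spectrum of (f1, f2): P = F1 * Conj(F2).
#   * Correlation surface of P:
#       S(dy, dx) = (1/(M1*M2)) * sum_{u,v} P(u,v) exp(-2i*pi*(u*dy/M1 + v*dx/M2))
#     which equals the circular cross-correlation sum_x f1(x) * f2(x + d).
#     Under the package-wide convention moving = reference translated by +d,
#     the surface therefore peaks at index d (wrapped).
#   * Signed frequencies / signed shifts: index p in [0, M) maps to
#     wrap_shift(p, M), i.e. p if p <= M/2 else p - M, range (-M/2, M/2].

#' Validate a real image matrix
#'
#' An image must be a numeric matrix of at least 2 x 2 finite values that is
#' not constant (a constant image carries no registrable structure).
#'
#' @param x object to validate.
#' @param arg name used in error messages.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop(sprintf("`%s` must be at least 2 x 2 (got %d x %d)",
                 arg, nrow(x), ncol(x)), call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(x))
    stop(sprintf("`%s` contains a non-finite value at row %d, column %d (1-based)",
                 arg, rc[1L], rc[2L]), call. = FALSE)
  }
  if (max(x) == min(x))
    stop(sprintf("`%s` is constant; a constant image cannot be registered", arg),
         call. = FALSE)
  invisible(x)
}

#' Wrap a 0-based index to a signed circular shift
#'
#' Peak indices live in `[0, extent)`; the corresponding signed shift is
#' `index` when `index <= extent/2` and `index - extent` otherwise, so the
#' result lies in `(-extent/2, extent/2]` with the boundary assigned to the
#' positive side.
#'
#' @param index integer vector of 0-based indices.
#' @param extent axis length.
#' @return signed integer shift(s).
#' @export
#' @examples
#' wrap_shift(c(0, 9, 8), 16)  # 0, -7, 8
wrap_shift <- function(index, extent) {
  if (any(index < 0 | index >= extent))
    stop(sprintf("index out of range [0, %d)", extent), call. = FALSE)
  ifelse(index <= extent / 2, index, index - extent)
}

# signed frequency of each machine-order DFT bin (Nyquist on the positive side)
signed_frequencies <- function(M) wrap_shift(0:(M - 1L), M)

#' Forward 2-D spectrum of an image
#'
#' Unnormalized forward DFT in machine frequency order; the DC coefficient is
#' the sum of pixel values and the round trip through the (1/(M1*M2)-scaled)
#' inverse transform reproduces the image to machine precision.
#'
#' @param image numeric matrix satisfying [validate_image()].
#' @return an object of class `sub_spectrum` with elements `values`
#'   (complex matrix) and `dim`.
#' @export
forward_spectrum <- function(image) {
  validate_image(image)
  structure(list(values = stats::fft(image), dim = dim(image)),
            class = "sub_spectrum")
}

# inverse of forward_spectrum on a complex matrix; asserts the imaginary
# residue is negligible relative to the signal before discarding it
inverse_transform <- function(values, tol = 1e-8) {
  z <- stats::fft(values, inverse = TRUE) / length(values)
  scale <- max(Mod(z), .Machine$double.eps)
  if (max(abs(Im(z))) / scale > tol)
    warning("inverse transform has a non-negligible imaginary part; ",
            "taking the real part", call. = FALSE)
  Re(z)
}

as_spectrum_values <- function(s, arg) {
  if (inherits(s, "sub_spectrum") || inherits(s, "sub_cross_spectrum")) return(s$values)
  if (is.matrix(s) && is.complex(s)) return(s)
  stop(sprintf("`%s` must be a spectrum object or a complex matrix", arg),
       call. = FALSE)
}

#' Cross-power spectrum of two spectra
#'
#' Entrywise `F1 * Conj(F2)`.  When `normalized`, each entry is divided by
#' its magnitude (pure phase), which turns the correlation surface into a
#' delta at the translation for exact circular shifts; entries whose
#' magnitude does not exceed `magnitude_floor` are set to 0 instead of being
#' divided (the spectrum of real images can have exact zeros).
#'
#' @param s1,s2 `sub_spectrum` objects (or complex matrices) of equal shape;
#'   `s2` is the spectrum of the moving image.
#' @param normalized divide each entry by its magnitude?
#' @param magnitude_floor threshold below which normalization is skipped;
#'   default `1e-12 *` the largest entry magnitude.
#' @return an object of class `sub_cross_spectrum` with elements `values`,
#'   `normalized`, `magnitude_floor`, `dim`.
#' @export
cross_power_spectrum <- function(s1, s2, normalized = TRUE,
                                 magnitude_floor = NULL) {
  v1 <- as_spectrum_values(s1, "s1")
  v2 <- as_spectrum_values(s2, "s2")
  if (!identical(dim(v1), dim(v2)))
    stop(sprintf("shape mismatch: s1 is %d x %d but s2 is %d x %d",
                 nrow(v1), ncol(v1), nrow(v2), ncol(v2)), call. = FALSE)
  p <- v1 * Conj(v2)
  floor_used <- 0
  if (normalized) {
    mag <- Mod(p)
    floor_used <- if (is.null(magnitude_floor)) 1e-12 * max(mag) else magnitude_floor
    keep <- mag > floor_used
    out <- matrix(0 + 0i, nrow(p), ncol(p))
    out[keep] <- p[keep] / mag[keep]
    p <- out
  }
  structure(list(values = p, normalized = isTRUE(normalized),
                 magnitude_floor = floor_used, dim = dim(p)),
            class = "sub_cross_spectrum")
}

#' Correlation surface of a cross-power spectrum
#'
#' Real part of the 1/(M1*M2)-scaled transform of the cross spectrum, equal
#' to the circular cross-correlation `sum_x f1(x) * f2(x + d)` (scaled).  For
#' a normalized cross spectrum of an exact integer circular shift the surface
#' is a unit impulse at the shift index.
#'
#' @param p `sub_cross_spectrum` (or complex matrix).
#' @return object of class `sub_surface`: `values` (real matrix) and
#'   `source_dim`.
#' @export
correlation_surface <- function(p) {
  v <- as_spectrum_values(p, "p")
  if (any(!is.finite(Re(v)) | !is.finite(Im(v))))
    stop("cross spectrum contains non-finite values", call. = FALSE)
  # forward-kernel evaluation of the lag sum (see conventions above)
  s <- Re(stats::fft(v)) / length(v)
  structure(list(values = s, source_dim = dim(v)), class = "sub_surface")
}

surface_values <- function(surface) {
  if (inherits(surface, "sub_surface")) surface$values
  else if (is.matrix(surface)) surface
  else stop("`surface` must be a sub_surface or a numeric matrix", call. = FALSE)
}

#' Locate the integer peak of a correlation surface
#'
#' Argmax of the surface, wrapped to a signed shift per axis.  Ties are
#' broken deterministically by the smallest row-major (row-first, 0-based)
#' index; a surface with no unique maximum is flagged rather than raised.
#'
#' @param surface `sub_surface` or real matrix.
#' @return list with `shift` (named `dy`, `dx`), `peak_value`, `unique`
#'   (logical: exactly one maximum), and `n_max` (number of tied maxima).
#' @export
locate_integer_peak <- function(surface) {
  vals <- surface_values(surface)
  if (length(vals) == 0L) stop("empty surface", call. = FALSE)
  if (any(!is.finite(vals))) stop("surface contains non-finite values", call. = FALSE)
  mx <- max(vals)
  hits <- which(vals == mx)
  rc <- arrayInd(hits, dim(vals)) - 1L          # 0-based (row, col)
  ord <- order(rc[, 1L], rc[, 2L])              # row-major tie rule
  best <- rc[ord[1L], ]
  list(shift = c(dy = wrap_shift(best[1L], nrow(vals)),
                 dx = wrap_shift(best[2L], ncol(vals))),
       peak_value = mx,
       unique = length(hits) == 1L,
       n_max = length(hits))
}

#' @export
print.sub_spectrum <- function(x, ...) {
  cat(sprintf("<sub_spectrum> %d x %d (DC = %s)\n",
              x$dim[1L], x$dim[2L], format(Re(x$values[1L, 1L]))))
  invisible(x)
}

#' @export
print.sub_cross_spectrum <- function(x, ...) {
  cat(sprintf("<sub_cross_spectrum> %d x %d, %s (magnitude floor %g)\n",
              x$dim[1L], x$dim[2L],
              if (x$normalized) "normalized" else "unnormalized",
              x$magnitude_floor))
  invisible(x)
}

#' @export
print.sub_surface <- function(x, ...) {
  pk <- locate_integer_peak(x)
  cat(sprintf("<sub_surface> %d x %d, peak %.6g at (dy = %d, dx = %d)\n",
              nrow(x$values), ncol(x$values), pk$peak_value,
              pk$shift[["dy"]], pk$shift[["dx"]]))
  invisible(x)
}
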