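# End-to-end registration: coarse stage -> fine stage -> combined shift
# (coarse + fine/epsilon), plus Fourier-shift warping and error helpers.

#' Registration configuration
#'
#' @param method `"improved"` (decimated coarse stage + bidirectional fine
#'   search) or `"baseline"` (the classic two-step algorithm: factor-2
#'   zero-padded coarse stage + full fine window).
#' @param upsample [upsample_config()] for the fine stage.
#' @param downsample [downsample_config()] for the improved coarse stage.
#' @param normalized_spectrum use the normalized (pure phase) cross spectrum
#'   in the fine stage and baseline coarse stage?  The decimated coarse
#'   stage always normalizes.
#' @return object of class `registration_config`.
#' @export
registration_config <- function(method = c("improved", "baseline"),
                                upsample = upsample_config(100L),
                                downsample = downsample_config(),
                                normalized_spectrum = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(upsample, "upsample_config"),
            inherits(downsample, "downsample_config"))
  structure(list(method = method, upsample = upsample, downsample = downsample,
                 normalized_spectrum = isTRUE(normalized_spectrum)),
            class = "registration_config")
}

#' Register a moving image against a reference
#'
#' Estimates the translation `(dy, dx)` such that the moving image equals
#' the reference translated by `+(dy, dx)` pixels (circular semantics).
#' The improved method localizes the peak of the decimated normalized
#' cross-power spectrum (disambiguating aliases against the full-resolution
#' spectrum when needed) and refines it on an upsampled window via the
#' bidirectional search; the baseline method uses the factor-2 zero-padded
#' coarse stage and the full window.  The combined estimate is
#' `coarse + fine_offset / epsilon`, quantized to `1/epsilon` pixel.
#'
#' @param reference,moving numeric image matrices of equal shape.
#' @param config [registration_config()].
#' @return object of class `registration_result` with elements `shift`
#'   (named numeric `(dy, dx)`), `coarse`, `fine`, `method`, `diagnostics`.
#' @export
register_translation <- function(reference, moving,
                                 config = registration_config()) {
  validate_image(reference, "reference")
  validate_image(moving, "moving")
  if (!identical(dim(reference), dim(moving)))
    stop(sprintf("shape mismatch: reference is %d x %d but moving is %d x %d",
                 nrow(reference), ncol(reference), nrow(moving), ncol(moving)),
         call. = FALSE)
  s1 <- forward_spectrum(reference)
  s2 <- forward_spectrum(moving)
  was_ambiguous <- FALSE
  if (config$method == "improved") {
    ce <- coarse_shift_decimated(s1, s2, config$downsample)
    was_ambiguous <- !ce$valid   # disambiguation actually required
    if (!ce$valid) {
      if (nrow(ce$candidates) > 0L) ce <- disambiguate_candidates(s1, s2, ce)
      if (!ce$valid)
        stop(paste0("coarse stage unresolvable: ",
                    if (ce$tie) "no unique decimated peak" else "no candidates",
                    sprintf(" (decimated surface %d x %d, peak %.4g)",
                            ce$decimated_dim[1L], ce$decimated_dim[2L],
                            ce$peak_value)), call. = FALSE)
    }
    center <- ce$shift
  } else {
    raw <- coarse_shift_baseline(s1, s2, config$normalized_spectrum)
    ce <- raw
    # fine window span 1.5 px covers the <= 0.5 px residual of rounding
    ce$shift <- round_half_away(raw$shift)
    ce$raw_shift <- raw$shift
    center <- ce$shift
  }
  p <- cross_power_spectrum(s1, s2, normalized = config$normalized_spectrum)
  fp <- if (config$method == "baseline" || config$upsample$search_mode == "full")
    full_window_argmax(p, center, config$upsample)
  else
    bidirectional_search(p, center, config$upsample)
  shift <- c(dy = unname(center[1L]) + fp$offset_pixels[["dy"]],
             dx = unname(center[2L]) + fp$offset_pixels[["dx"]])
  structure(list(shift = shift, coarse = ce, fine = fp,
                 method = config$method, config = config,
                 diagnostics = list(peak_value = fp$peak_value,
                                    fallback = fp$fallback,
                                    evaluations = fp$evaluations,
                                    window_dim = fp$window_dim,
                                    decimated_dim = ce$decimated_dim,
                                    coarse_ambiguous = was_ambiguous,
                                    coarse_tie = ce$tie)),
            class = "registration_result")
}

#' Translate an image by a (possibly fractional) shift
#'
#' Multiplies the spectrum by the translation phase ramp and inverts;
#' boundaries are circular (periodic).  At integer shifts this is exactly a
#' circular roll of the pixel array.  For even extents the Nyquist bin's
#' ramp is replaced by its real part so that fractionally shifted real
#' images remain exactly real (identical at integer shifts; for band-limited
#' images, which carry no Nyquist energy, the operation is exact at any
#' shift).
#'
#' @param image numeric matrix.
#' @param shift numeric `(dy, dx)` in pixels; the result is `image`
#'   translated by `+shift` under the package convention.
#' @return the translated image matrix.
#' @export
apply_shift <- function(image, shift) {
  if (length(shift) != 2L || any(!is.finite(shift)))
    stop("`shift` must be two finite numbers (dy, dx)", call. = FALSE)
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  M1 <- nrow(image); M2 <- ncol(image)
  ramp_axis <- function(M, d) {
    e <- exp(-2i * pi * signed_frequencies(M) * d / M)
    if (M %% 2L == 0L) e[M %/% 2L + 1L] <- cos(pi * d)   # keep spectrum Hermitian
    e
  }
  g <- stats::fft(image) * outer(ramp_axis(M1, shift[1L]), ramp_axis(M2, shift[2L]))
  inverse_transform(g)
}

#' Per-axis and Euclidean shift error
#'
#' @param estimate,truth numeric `(dy, dx)` shifts in pixels.
#' @return named numeric: `dy`, `dx` (absolute per-axis errors) and
#'   `euclidean` (2-norm), all in pixels.
#' @export
shift_error <- function(estimate, truth) {
  d <- abs(as.numeric(estimate)[1:2] - as.numeric(truth)[1:2])
  c(dy = d[1L], dx = d[2L], euclidean = sqrt(sum(d^2)))
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s method\n", x$method))
  cat(sprintf("  shift: dy = %.6g, dx = %.6g px  (moving = reference translated by +shift)\n",
              x$shift[["dy"]], x$shift[["dx"]]))
  cat(sprintf("  coarse (dy = %g, dx = %g) + fine (%+g, %+g)/%d\n",
              x$coarse$shift[["dy"]], x$coarse$shift[["dx"]],
              x$fine$offset_upsampled[["dy"]], x$fine$offset_upsampled[["dx"]],
              x$fine$epsilon))
  cat(sprintf("  peak %.6g; %d window entries evaluated%s%s\n",
              x$diagnostics$peak_value, x$diagnostics$evaluations,
              if (x$diagnostics$fallback) "; search fallback" else "",
              if (x$diagnostics$coarse_ambiguous) "; coarse aliasing resolved" else ""))
  invisible(x)
}
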