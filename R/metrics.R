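# Registration quality metrics: scale-minimized NRMSE and the RMS
# gray-value target registration error.

check_same_shape <- function(a, b, na = "first image", nb = "second image") {
  if (!is.matrix(a) || !is.numeric(a) || !is.matrix(b) || !is.numeric(b))
    stop("both inputs must be numeric matrices", call. = FALSE)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s is %d x %d but %s is %d x %d",
                 na, nrow(a), ncol(a), nb, nrow(b), ncol(b)), call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("images must be finite", call. = FALSE)
  invisible(NULL)
}

#' Normalized root-mean-square error between two images
#'
#' `E^2 = min_alpha sum((alpha*g - f1)^2) / sum(f1^2)` with the closed-form
#' optimum `alpha = sum(f1*g)/sum(g^2)`, equivalently
#' `E^2 = 1 - (sum(f1*g))^2 / (sum(g^2) * sum(f1^2))`, so the metric is
#' invariant to a positive rescaling of `f2`.  When `shift` is supplied,
#' `g` is `f2` translated back by `-shift` (the registration's alignment)
#' before comparison; the translation is not re-optimized inside the metric.
#'
#' @param f1 reference image matrix.
#' @param f2 comparison image matrix of the same shape.
#' @param shift optional `(dy, dx)` translation of `f2` relative to `f1`
#'   (e.g. a registration estimate) undone before comparison.
#' @return list with `nrmse` (in `[0, 1]`), `alpha` (optimal intensity
#'   scale) and `n_pixels`.
#' @export
nrmse <- function(f1, f2, shift = NULL) {
  check_same_shape(f1, f2, "f1", "f2")
  g <- if (is.null(shift)) f2 else apply_shift(f2, -shift)
  sf <- sum(f1^2)
  if (sf == 0) stop("degenerate reference: sum of squared values is zero",
                    call. = FALSE)
  sg <- sum(g^2)
  cross <- sum(f1 * g)
  alpha <- if (sg > 0) cross / sg else 0
  e2 <- 1 - if (sg > 0) cross^2 / (sg * sf) else 0
  list(nrmse = sqrt(max(e2, 0)), alpha = alpha, n_pixels = length(f1))
}

#' Target registration error (RMS gray-value difference)
#'
#' `sqrt(mean((i1 - i2)^2))` over the full image domain: the smaller the
#' value, the closer the gray values of corresponding pixels and the better
#' the registration.
#'
#' @param i1,i2 image matrices of equal shape.
#' @return a non-negative scalar in intensity units.
#' @export
target_registration_error <- function(i1, i2) {
  check_same_shape(i1, i2, "i1", "i2")
  sqrt(mean((i1 - i2)^2))
}

#' Combined metric report
#'
#' Convenience wrapper computing NRMSE and the target registration error
#' between a reference and a moving image, optionally after undoing an
#' estimated shift.
#'
#' @inheritParams nrmse
#' @param reference,moving image matrices of equal shape.
#' @return object of class `metric_report`: `nrmse`, `alpha`, `the_value`,
#'   `n_pixels`.
#' @export
metric_report <- function(reference, moving, shift = NULL) {
  nr <- nrmse(reference, moving, shift)
  aligned <- if (is.null(shift)) moving else apply_shift(moving, -shift)
  structure(list(nrmse = nr$nrmse, alpha = nr$alpha,
                 the_value = target_registration_error(reference, aligned),
                 n_pixels = nr$n_pixels),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> NRMSE = %.6g (alpha = %.6g), THE = %.6g over %d px\n",
              x$nrmse, x$alpha, x$the_value, x$n_pixels))
  invisible(x)
}
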