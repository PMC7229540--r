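# Synthetic benchmark generator: band-limited random phantoms, subpixel
# shifted pairs with exact Fourier-shift ground truth, noise injection, and
# a seeded benchmark harness.
#
# Band limitation is what makes the ground truth exact: a phantom with no
# energy at or above its spectral cutoff is translated *exactly* by the
# phase-ramp multiplication for any real-valued shift, so benchmark errors
# are attributable entirely to the estimator.

#' Generate a band-limited random phantom
#'
#' A seeded Gaussian random field is hard low-pass filtered to
#' `|frequency| <= smoothness * Nyquist` per axis and rescaled to exactly
#' `[0, 1]`.
#'
#' @param size image extent: a scalar (square) or `(M1, M2)`, each at
#'   least 32.
#' @param seed integer seed; the same seed always yields the same phantom
#'   and the caller's RNG state is left untouched.
#' @param smoothness fraction of the spectrum retained per axis, in
#'   `(0, 0.5]`; smaller values give smoother images.
#' @return an image matrix in `[0, 1]`.
#' @export
make_phantom <- function(size, seed, smoothness = 0.25) {
  size <- as.integer(rep(size, length.out = 2L))
  if (any(size < 32L)) stop("`size` must be at least 32 per axis", call. = FALSE)
  if (smoothness <= 0 || smoothness > 0.5)
    stop("`smoothness` must be in (0, 0.5]", call. = FALSE)
  z <- with_seed(seed, matrix(stats::rnorm(prod(size)), size[1L], size[2L]))
  f <- stats::fft(z)
  keep_r <- abs(signed_frequencies(size[1L])) <= smoothness * size[1L] / 2
  keep_c <- abs(signed_frequencies(size[2L])) <= smoothness * size[2L] / 2
  f[!outer(keep_r, keep_c)] <- 0
  x <- inverse_transform(f)
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate phantom (constant field)", call. = FALSE)
  (x - rng[1L]) / diff(rng)
}

#' Build a shifted image pair with known ground truth
#'
#' The moving image is the phantom translated by `truth` via the Fourier
#' phase ramp (circular boundaries), plus optional seeded additive Gaussian
#' noise with standard deviation `noise_sigma` times the phantom's dynamic
#' range.
#'
#' @param phantom reference image matrix.
#' @param truth numeric `(dy, dx)` shift in pixels.
#' @param noise_sigma noise level as a fraction of the dynamic range
#'   (`0` = noiseless).
#' @param seed seed for the noise realization.
#' @return object of class `synthetic_case`: `reference`, `moving`,
#'   `truth`, `noise_sigma`, `seed`, `size`.
#' @export
make_shifted_pair <- function(phantom, truth, noise_sigma = 0, seed = 0L) {
  validate_image(phantom, "phantom")
  if (length(truth) != 2L || any(!is.finite(truth)))
    stop("`truth` must be two finite numbers (dy, dx)", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  moving <- apply_shift(phantom, truth)
  if (noise_sigma > 0) {
    sd_noise <- noise_sigma * diff(range(phantom))
    moving <- moving + with_seed(seed,
      matrix(stats::rnorm(length(phantom), sd = sd_noise),
             nrow(phantom), ncol(phantom)))
  }
  structure(list(reference = phantom, moving = moving,
                 truth = c(dy = unname(truth[1L]), dx = unname(truth[2L])),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 size = dim(phantom)),
            class = "synthetic_case")
}

#' Write a synthetic case to disk
#'
#' Writes `reference.tif` and `moving.tif` (16-bit grayscale TIFF) plus a
#' `case.json` sidecar recording the ground truth, seed, noise level, size
#' and the shift convention.
#'
#' @param case a `synthetic_case`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(reference = file.path(dir, "reference.tif"),
             moving = file.path(dir, "moving.tif"),
             sidecar = file.path(dir, "case.json"))
  save_image(case$reference, paths[["reference"]], bits = 16L)
  save_image(case$moving, paths[["moving"]], bits = 16L)
  jsonlite::write_json(
    list(truth = as.list(case$truth), noise_sigma = case$noise_sigma,
         seed = case$seed, size = as.integer(case$size),
         convention = "moving = reference translated by +truth (dy = rows, dx = cols), circular boundaries"),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run a seeded registration benchmark suite
#'
#' Generates `n_cases` shifted pairs per image size (shifts uniform per axis
#' in `[-shift_range, shift_range]`), registers every case with the given
#' configuration, and aggregates per-axis errors.  Fully deterministic in
#' `seed`; failed cases are recorded per row, not raised.
#'
#' @param sizes integer vector of square image extents.
#' @param n_cases cases per size.
#' @param shift_range per-axis shift bound in pixels.
#' @param noise_sigma additive noise level (fraction of dynamic range).
#' @param seed integer master seed.
#' @param config [registration_config()].
#' @param smoothness phantom band limit, see [make_phantom()].
#' @param csv,json optional output paths for the per-case table and the
#'   summary.
#' @return object of class `suite_summary`: `cases` (data frame, one row
#'   per case), `summary` (aggregates), `config`, `seed`.
#' @export
benchmark_suite <- function(sizes = c(64L, 128L, 256L, 512L), n_cases = 20L,
                            shift_range = 10, noise_sigma = 0, seed = 1L,
                            config = registration_config(),
                            smoothness = 0.25, csv = NULL, json = NULL) {
  stopifnot(n_cases >= 1L, shift_range >= 0, length(sizes) >= 1L)
  draws <- with_seed(seed, list(
    phantom_seeds = sample.int(2^30, length(sizes)),
    noise_seeds = matrix(sample.int(2^30, length(sizes) * n_cases),
                         length(sizes), n_cases),
    shifts = array(stats::runif(length(sizes) * n_cases * 2L,
                                -shift_range, shift_range),
                   dim = c(length(sizes), n_cases, 2L))))
  rows <- vector("list", length(sizes) * n_cases)
  i <- 0L
  for (si in seq_along(sizes)) {
    phantom <- make_phantom(sizes[si], draws$phantom_seeds[si], smoothness)
    for (ci in seq_len(n_cases)) {
      i <- i + 1L
      truth <- draws$shifts[si, ci, ]
      case <- make_shifted_pair(phantom, truth, noise_sigma,
                                draws$noise_seeds[si, ci])
      res <- tryCatch(register_translation(case$reference, case$moving, config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[i]] <- data.frame(size = sizes[si], case = ci,
                                true_dy = truth[1L], true_dx = truth[2L],
                                est_dy = NA_real_, est_dx = NA_real_,
                                err_dy = NA_real_, err_dx = NA_real_,
                                err_euclidean = NA_real_,
                                fallback = NA, ambiguous = NA,
                                evaluations = NA_integer_,
                                error = conditionMessage(res))
      } else {
        err <- shift_error(res$shift, truth)
        rows[[i]] <- data.frame(size = sizes[si], case = ci,
                                true_dy = truth[1L], true_dx = truth[2L],
                                est_dy = res$shift[["dy"]], est_dx = res$shift[["dx"]],
                                err_dy = err[["dy"]], err_dx = err[["dx"]],
                                err_euclidean = err[["euclidean"]],
                                fallback = res$diagnostics$fallback,
                                ambiguous = res$diagnostics$coarse_ambiguous,
                                evaluations = res$diagnostics$evaluations,
                                error = NA_character_)
      }
    }
  }
  cases <- do.call(rbind, rows)
  ok <- is.na(cases$error)
  per_axis <- c(cases$err_dy[ok], cases$err_dx[ok])
  summary <- list(
    n_cases = nrow(cases), n_failed = sum(!ok),
    mean_abs_error = if (length(per_axis)) mean(per_axis) else NA_real_,
    max_abs_error = if (length(per_axis)) max(per_axis) else NA_real_,
    mean_err_dy = mean(cases$err_dy[ok]), mean_err_dx = mean(cases$err_dx[ok]),
    fallbacks = sum(cases$fallback[ok]), ambiguous = sum(cases$ambiguous[ok]),
    method = config$method, epsilon = config$upsample$epsilon,
    noise_sigma = noise_sigma, shift_range = shift_range, seed = seed)
  if (!is.null(csv)) utils::write.csv(cases, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(summary, json, auto_unbox = TRUE,
                                           digits = NA)
  structure(list(cases = cases, summary = summary, config = config, seed = seed),
            class = "suite_summary")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %d x %d, truth (dy = %g, dx = %g), noise %g, seed %d\n",
              x$size[1L], x$size[2L], x$truth[["dy"]], x$truth[["dx"]],
              x$noise_sigma, x$seed))
  invisible(x)
}

#' @export
print.suite_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<suite_summary> %d cases (%s, epsilon = %d, noise %g)\n",
              s$n_cases, s$method, s$epsilon, s$noise_sigma))
  cat(sprintf("  mean |error| %.3g px, max |error| %.3g px per axis\n",
              s$mean_abs_error, s$max_abs_error))
  cat(sprintf("  %d fallbacks, %d ambiguous coarse stages, %d failures\n",
              s$fallbacks, s$ambiguous, s$n_failed))
  invisible(x)
}
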