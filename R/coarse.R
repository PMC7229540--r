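# Coarse pixel-level localization from the K-decimated cross-power spectrum.
#
# Keeping every K-th spectral sample per axis (index 0, the DC sample, always
# kept) makes the inverse transform the sum of the K1*K2 aliased periodic
# replicas of the full correlation surface, with period (M1/K1, M2/K2).  For
# a *normalized* spectrum the surface is (near) a delta, so the replicas do
# not interact and the peak survives decimation whenever the true shift lies
# inside half the aliasing period; outside it the peak position is only known
# modulo M/K and must be disambiguated against the full-resolution spectrum.

#' Decimation configuration for the coarse stage
#'
#' @param k1,k2 integer decimation factors along rows and columns; each must
#'   divide the corresponding image extent.  `k2` defaults to `k1`.
#' @param auto if `TRUE` (the default when no factors are given), choose K
#'   per axis as `M/32` when `M >= 64` and `M` is divisible by 32, otherwise
#'   the largest divisor of `M` leaving a decimated extent of at least 32.
#' @return object of class `downsample_config`.
#' @export
downsample_config <- function(k1 = NULL, k2 = k1, auto = is.null(k1)) {
  if (!auto) {
    if (is.null(k1)) stop("either set `auto = TRUE` or give `k1`", call. = FALSE)
    k1 <- as.integer(k1); k2 <- as.integer(k2)
    if (k1 < 1L || k2 < 1L) stop("decimation factors must be >= 1", call. = FALSE)
  }
  structure(list(k1 = k1, k2 = k2, auto = isTRUE(auto)),
            class = "downsample_config")
}

auto_decimation <- function(M) {
  if (M >= 64L && M %% 32L == 0L) return(as.integer(M %/% 32L))
  divs <- seq_len(M)[M %% seq_len(M) == 0L]
  max(divs[M %/% divs >= 32L], 1L)
}

# resolve (k1, k2) against an image shape, enforcing divisibility and a
# minimum decimated extent of 4 samples per axis
resolve_decimation <- function(cfg, dim) {
  stopifnot(inherits(cfg, "downsample_config"))
  k <- if (cfg$auto) c(auto_decimation(dim[1L]), auto_decimation(dim[2L]))
       else c(cfg$k1, cfg$k2)
  for (ax in 1:2) {
    M <- dim[ax]
    if (M %% k[ax] != 0L) {
      divs <- seq_len(M)[M %% seq_len(M) == 0L]
      near <- divs[which.min(abs(divs - k[ax]))]
      stop(sprintf("decimation factor %d does not divide extent %d; nearest divisor is %d",
                   k[ax], M, near), call. = FALSE)
    }
    if (M %/% k[ax] < 4L)
      stop(sprintf("decimated extent %d/%d = %d is below the minimum of 4",
                   M, k[ax], M %/% k[ax]), call. = FALSE)
  }
  as.integer(k)
}

#' Decimate a normalized cross-power spectrum
#'
#' Returns the submatrix at indices `(k1*m, k2*n)` (0-based; DC always kept).
#' Decimating an *unnormalized* spectrum is refused: its aliased correlation
#' replicas carry image-dependent magnitudes whose overlap can move the peak,
#' which is precisely what normalization prevents.
#'
#' @param p normalized `sub_cross_spectrum`.
#' @param cfg [downsample_config()].
#' @return `sub_cross_spectrum` of shape `(M1/k1, M2/k2)`.
#' @export
decimate_cross_spectrum <- function(p, cfg = downsample_config()) {
  stopifnot(inherits(p, "sub_cross_spectrum"))
  if (!p$normalized)
    stop("refusing to decimate an unnormalized cross spectrum: overlapping ",
         "aliased correlation replicas could displace the peak; normalize first",
         call. = FALSE)
  k <- resolve_decimation(cfg, p$dim)
  sub <- p$values[seq(1L, p$dim[1L], by = k[1L]),
                  seq(1L, p$dim[2L], by = k[2L]), drop = FALSE]
  structure(list(values = sub, normalized = TRUE,
                 magnitude_floor = p$magnitude_floor, dim = dim(sub)),
            class = "sub_cross_spectrum")
}

# alias grid of a decimated peak: all shifts congruent to `shift` modulo the
# aliasing period, wrapped into (-M/2, M/2], sorted ascending (row-major)
alias_candidates <- function(shift, m, M) {
  one_axis <- function(s, period, extent) {
    v <- s + period * (0:(extent %/% period - 1L))
    sort(unique(wrap_shift(v %% extent, extent)))
  }
  dy <- one_axis(shift[1L], m[1L], M[1L])
  dx <- one_axis(shift[2L], m[2L], M[2L])
  out <- cbind(dy = rep(dy, each = length(dx)), dx = rep(dx, length(dy)))
  out
}

new_coarse_estimate <- function(shift, valid, ambiguous, candidates,
                                peak_value, tie, k, decimated_dim, source_dim,
                                stage) {
  structure(list(shift = shift, valid = valid, ambiguous = ambiguous,
                 candidates = candidates, peak_value = peak_value, tie = tie,
                 k = k, decimated_dim = decimated_dim, source_dim = source_dim,
                 stage = stage),
            class = "coarse_estimate")
}

#' Coarse shift from the decimated cross-power spectrum
#'
#' Builds the normalized cross spectrum of the two images, decimates it,
#' inverts the small matrix and locates the wrapped peak.  The estimate is
#' `valid` only when the peak is unique and lies strictly inside the
#' conservative bound `|d| < M/(2K) - 1` per axis (beyond half the aliasing
#' period the wrapped sign is ambiguous).  Whenever decimation creates
#' aliases (K > 1) the full alias grid is attached as `candidates` and the
#' estimate is flagged `ambiguous`: the decimated surface alone cannot
#' distinguish a true in-bound shift from an out-of-bound alias, so callers
#' whose shifts may exceed the bound should verify via
#' [disambiguate_candidates()].
#'
#' @param s1,s2 `sub_spectrum` objects of the reference and moving images.
#' @param cfg [downsample_config()].
#' @return object of class `coarse_estimate` with elements `shift` (named
#'   integer vector), `valid`, `ambiguous`, `candidates`, `peak_value`,
#'   `tie`, `k`, `decimated_dim`.
#' @export
coarse_shift_decimated <- function(s1, s2, cfg = downsample_config()) {
  if (!identical(s1$dim, s2$dim))
    stop(sprintf("shape mismatch: s1 is %d x %d but s2 is %d x %d",
                 s1$dim[1L], s1$dim[2L], s2$dim[1L], s2$dim[2L]), call. = FALSE)
  k <- resolve_decimation(cfg, s1$dim)
  p <- cross_power_spectrum(s1, s2, normalized = TRUE)
  pd <- decimate_cross_spectrum(p, downsample_config(k[1L], k[2L], auto = FALSE))
  pk <- locate_integer_peak(correlation_surface(pd))
  m <- pd$dim
  inside <- abs(pk$shift[["dy"]]) < m[1L] / 2 - 1 &&
            abs(pk$shift[["dx"]]) < m[2L] / 2 - 1
  valid <- pk$unique && inside
  # a decimated peak is only known modulo the aliasing period: whenever
  # aliases exist the full grid is attached so callers can verify or recover
  # out-of-bound shifts; `valid` asserts usability under the in-bound
  # assumption, not the absence of aliases
  cand <- alias_candidates(pk$shift, m, s1$dim)
  ambiguous <- nrow(cand) > 1L || !valid
  if (nrow(cand) <= 1L && valid)
    cand <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("dy", "dx")))
  new_coarse_estimate(shift = pk$shift, valid = valid, ambiguous = ambiguous,
                      candidates = cand, peak_value = pk$peak_value,
                      tie = !pk$unique, k = k, decimated_dim = m,
                      source_dim = s1$dim, stage = "decimated")
}

#' Resolve an aliasing-ambiguous coarse estimate
#'
#' Evaluates the full-resolution unnormalized circular correlation at each
#' candidate shift by direct exponential-weighted summation over the cross
#' spectrum (a handful of single-point sums; no full inverse FFT) and keeps
#' the candidate with the largest real value.  Ties go to the smallest
#' row-major candidate and are reported via `tie`.
#'
#' @param s1,s2 `sub_spectrum` objects of the two images.
#' @param est an ambiguous `coarse_estimate`.
#' @return the estimate with `shift` replaced by the winning candidate,
#'   `valid = TRUE`, `ambiguous = FALSE`, and the per-candidate correlation
#'   values in `candidate_values`.
#' @export
disambiguate_candidates <- function(s1, s2, est) {
  stopifnot(inherits(est, "coarse_estimate"))
  if (nrow(est$candidates) == 0L)
    stop("coarse estimate has no candidates to disambiguate", call. = FALSE)
  if (nrow(est$candidates) == 1L) {
    est$shift <- c(dy = est$candidates[1L, "dy"], dx = est$candidates[1L, "dx"])
    est$valid <- TRUE; est$ambiguous <- FALSE
    return(est)
  }
  p <- cross_power_spectrum(s1, s2, normalized = FALSE)
  vals <- vapply(seq_len(nrow(est$candidates)), function(i)
    Re(upsampled_value(p, est$candidates[i, "dy"], est$candidates[i, "dx"])),
    numeric(1L))
  best <- which(vals == max(vals))[1L]       # candidates are in row-major order
  est$shift <- c(dy = est$candidates[best, "dy"], dx = est$candidates[best, "dx"])
  est$valid <- TRUE
  est$ambiguous <- FALSE
  est$tie <- sum(vals == max(vals)) > 1L
  est$candidate_values <- vals
  est
}

#' Reference coarse stage: factor-2 zero-padded cross-correlation
#'
#' The classic first stage of the two-step upsampled cross-correlation
#' algorithm: the cross spectrum is embedded (at its signed frequencies)
#' into a `2*M1 x 2*M2` zero matrix, transformed, and the wrapped peak index
#' halved, giving a half-pixel-resolution estimate.
#'
#' @param s1,s2 `sub_spectrum` objects of the two images.
#' @param normalized use the normalized (pure phase) cross spectrum?
#' @return `coarse_estimate` whose `shift` is real-valued on the half-pixel
#'   grid.
#' @export
coarse_shift_baseline <- function(s1, s2, normalized = TRUE) {
  if (!identical(s1$dim, s2$dim))
    stop(sprintf("shape mismatch: s1 is %d x %d but s2 is %d x %d",
                 s1$dim[1L], s1$dim[2L], s2$dim[1L], s2$dim[2L]), call. = FALSE)
  p <- cross_power_spectrum(s1, s2, normalized = normalized)
  M <- p$dim
  big <- matrix(0 + 0i, 2L * M[1L], 2L * M[2L])
  rows <- (signed_frequencies(M[1L]) %% (2L * M[1L])) + 1L
  cols <- (signed_frequencies(M[2L]) %% (2L * M[2L])) + 1L
  big[rows, cols] <- p$values
  s <- Re(stats::fft(big)) / (M[1L] * M[2L])
  pk <- locate_integer_peak(s)               # wrap at extent 2*M, lag grid 1/2 px
  new_coarse_estimate(shift = pk$shift / 2, valid = pk$unique, ambiguous = FALSE,
                      candidates = matrix(integer(0), 0L, 2L,
                                          dimnames = list(NULL, c("dy", "dx"))),
                      peak_value = pk$peak_value, tie = !pk$unique,
                      k = c(1L, 1L), decimated_dim = dim(big),
                      source_dim = M, stage = "baseline")
}

#' @export
print.coarse_estimate <- function(x, ...) {
  cat(sprintf("<coarse_estimate> (%s) shift (dy = %g, dx = %g), %s%s\n",
              x$stage, x$shift[["dy"]], x$shift[["dx"]],
              if (x$valid) "valid" else "not valid",
              if (x$ambiguous) sprintf(", %d aliasing candidates", nrow(x$candidates)) else ""))
  invisible(x)
}
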