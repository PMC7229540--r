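# Fine subpixel localization: the upsampled cross-correlation on a small lag
# window around the coarse estimate, evaluated directly as a product of three
# DFT matrices A (W x M1) * P (M1 x M2) * C (M2 x W) instead of a globally
# zero-padded inverse FFT.  Window sample (r, c) corresponds to the lag
#   (center_dy + (r - floor(W/2))/epsilon, center_dx + (c - floor(W/2))/epsilon)
# so zero lag is always on the grid and the window spans ~1.5 px at the
# default span.  The window is realized row-lazily: D = P * C is computed
# once, after which any row is a single vector-matrix product, which is what
# makes the bidirectional search cheap.  All-zero rows/columns of P (band
# limited or floored spectra) are dropped from the products; this is exact.

#' Upsampling configuration for the fine stage
#'
#' @param epsilon positive integer upsampling factor; the fine estimate is
#'   quantized to `1/epsilon` pixel.
#' @param window_span window size in pixels per axis (default 1.5, enough to
#'   cover the at-most-0.75 px residual of a rounded coarse estimate).
#' @param step_fraction row-search step as a fraction of `epsilon`
#'   (default 0.3); the step is `max(1, round(step_fraction * epsilon))`
#'   grid units.
#' @param search_mode `"bidirectional"` (outward row probing, then a bracket
#'   scan) or `"full"` (evaluate the whole window).
#' @return object of class `upsample_config` with derived fields
#'   `window_dim` (W) and `step`.
#' @export
upsample_config <- function(epsilon, window_span = 1.5, step_fraction = 0.3,
                            search_mode = c("bidirectional", "full")) {
  search_mode <- match.arg(search_mode)
  epsilon <- as.integer(epsilon)
  if (epsilon < 1L) stop("`epsilon` must be a positive integer", call. = FALSE)
  if (window_span <= 0) stop("`window_span` must be positive", call. = FALSE)
  if (step_fraction <= 0 || step_fraction > 1)
    stop("`step_fraction` must be in (0, 1]", call. = FALSE)
  W <- as.integer(ceiling(window_span * epsilon))
  if (W < 3L)
    stop(sprintf("window of %d samples is too small; need window_span * epsilon >= 3", W),
         call. = FALSE)
  step <- max(1L, as.integer(round(step_fraction * epsilon)))
  if (step >= W / 2)
    stop(sprintf("search step %d must be smaller than half the window (%d)", step, W),
         call. = FALSE)
  structure(list(epsilon = epsilon, window_span = window_span,
                 step_fraction = step_fraction, search_mode = search_mode,
                 window_dim = W, step = step),
            class = "upsample_config")
}

# lags (in pixels) of the window samples along one axis
window_lags <- function(cfg, center) {
  W <- cfg$window_dim
  center + ((0:(W - 1L)) - W %/% 2L) / cfg$epsilon
}

#' Row factor of the three-matrix DFT window
#'
#' Entry `(r, u)` is `exp(-2i*pi * d_y(r) * u' / M1)` where `d_y(r)` is the
#' lag of window row `r` (see [upsample_config()]) and `u'` the signed
#' frequency of machine bin `u`.  The column factor is the transpose of the
#' same construction applied along the other axis.
#'
#' @param cfg [upsample_config()].
#' @param center_dy window center (pixels) along the row axis.
#' @param M1 image extent along the row axis.
#' @param rows 0-based window row indices (default: all).
#' @return complex matrix `length(rows) x M1`.
#' @export
dft_row_factor <- function(cfg, center_dy, M1, rows = 0:(cfg$window_dim - 1L)) {
  if (any(rows < 0L | rows >= cfg$window_dim))
    stop("window row index out of range", call. = FALSE)
  lags <- window_lags(cfg, center_dy)[rows + 1L]
  exp(-2i * pi * outer(lags, signed_frequencies(M1)) / M1)
}

#' Single-point upsampled correlation value
#'
#' The exponential-weighted sum `sum_{u,v} P(u,v) exp(-2i*pi*(u' dy/M1 + v' dx/M2))`
#' over signed frequencies: the cross-correlation at one (possibly
#' fractional) lag, unnormalized (at integer lags it equals `M1*M2` times
#' the [correlation_surface()] value).  Building block of the window
#' factors, the disambiguation step, and the test oracles.
#'
#' @param p full-resolution `sub_cross_spectrum`.
#' @param dy,dx lag in pixels (real-valued).
#' @return a complex scalar.
#' @export
upsampled_value <- function(p, dy, dx) {
  stopifnot(inherits(p, "sub_cross_spectrum") || is.matrix(p))
  v <- as_spectrum_values(p, "p")
  a <- exp(-2i * pi * signed_frequencies(nrow(v)) * dy / nrow(v))
  b <- exp(-2i * pi * signed_frequencies(ncol(v)) * dx / ncol(v))
  drop(rbind(a) %*% v %*% cbind(b))
}

#' Create an empty lazy upsampled window
#'
#' @param p full-resolution `sub_cross_spectrum`.
#' @param center window center shift (numeric `(dy, dx)`, pixels).
#' @param cfg [upsample_config()].
#' @return object of class `upsampled_window`; rows are filled by
#'   [evaluate_window_rows()].
#' @export
new_upsampled_window <- function(p, center, cfg) {
  stopifnot(inherits(p, "sub_cross_spectrum"), inherits(cfg, "upsample_config"))
  W <- cfg$window_dim
  structure(list(values = matrix(NA_complex_, W, W),
                 row_done = logical(W),
                 center = c(dy = unname(center[1L]), dx = unname(center[2L])),
                 epsilon = cfg$epsilon, cfg = cfg, dim = p$dim,
                 evaluations = 0L, D = NULL, nzr = NULL),
            class = "upsampled_window")
}

#' Evaluate selected rows of an upsampled window
#'
#' Fills the requested (0-based) rows of the window by the three-matrix
#' product, caching `D = P %*% C` on first use so each further row costs one
#' vector-matrix product.  Already-evaluated rows are not recomputed and do
#' not increment the evaluation count.
#'
#' @param p the `sub_cross_spectrum` the window was created from.
#' @param w an `upsampled_window`.
#' @param rows 0-based row indices.
#' @return the updated window.
#' @export
evaluate_window_rows <- function(p, w, rows) {
  stopifnot(inherits(w, "upsampled_window"))
  W <- w$cfg$window_dim
  rows <- unique(as.integer(rows))
  if (any(rows < 0L | rows >= W)) stop("window row index out of range", call. = FALSE)
  new <- rows[!w$row_done[rows + 1L]]
  if (length(new) == 0L) return(w)
  if (is.null(w$D)) {
    mag <- Mod(p$values)
    nzr <- which(rowSums(mag) > 0)
    nzc <- which(colSums(mag) > 0)
    if (length(nzr) == 0L) { nzr <- 1L; nzc <- 1L }   # degenerate all-zero spectrum
    dcol <- window_lags(w$cfg, w$center[["dx"]])
    C <- exp(-2i * pi * outer(signed_frequencies(p$dim[2L])[nzc], dcol) / p$dim[2L])
    w$D <- p$values[nzr, nzc, drop = FALSE] %*% C
    w$nzr <- nzr
  }
  drow <- window_lags(w$cfg, w$center[["dy"]])[new + 1L]
  A <- exp(-2i * pi * outer(drow, signed_frequencies(p$dim[1L])[w$nzr]) / p$dim[1L])
  w$values[new + 1L, ] <- A %*% w$D
  w$row_done[new + 1L] <- TRUE
  w$evaluations <- w$evaluations + length(new) * W
  w
}

# argmax of the real part over evaluated entries; row-major tie rule.
# Returns 0-based window indices.
window_argmax <- function(w) {
  done <- which(w$row_done)
  re <- Re(w$values[done, , drop = FALSE])
  mx <- max(re)
  hits <- which(re == mx)
  rc <- arrayInd(hits, dim(re))
  rc[, 1L] <- done[rc[, 1L]]                  # back to full-window row index
  ord <- order(rc[, 1L], rc[, 2L])
  c(row = rc[ord[1L], 1L] - 1L, col = rc[ord[1L], 2L] - 1L, value = mx,
    n_max = length(hits))
}

new_fine_peak <- function(w, am, fallback) {
  W <- w$cfg$window_dim
  off <- c(dy = unname(am[["row"]]) - W %/% 2L, dx = unname(am[["col"]]) - W %/% 2L)
  structure(list(offset_upsampled = off,
                 offset_pixels = off / w$epsilon,
                 peak_value = unname(am[["value"]]),
                 evaluations = w$evaluations,
                 tie = am[["n_max"]] > 1L,
                 fallback = fallback,
                 window_dim = W, epsilon = w$epsilon, center = w$center),
            class = "fine_peak")
}

#' Full-window argmax (reference fine stage)
#'
#' Evaluates the complete `W x W` window by the three-matrix product and
#' returns its peak.  This is both the baseline fine stage and the oracle
#' the bidirectional search is checked against.
#'
#' @param p full-resolution `sub_cross_spectrum`.
#' @param center window center shift (pixels).
#' @param cfg [upsample_config()].
#' @return object of class `fine_peak`: `offset_upsampled` (integer, units
#'   `1/epsilon` px, relative to the window center), `offset_pixels`,
#'   `peak_value`, `evaluations`, `fallback`.
#' @export
full_window_argmax <- function(p, center, cfg) {
  w <- new_upsampled_window(p, center, cfg)
  w <- evaluate_window_rows(p, w, 0:(cfg$window_dim - 1L))
  new_fine_peak(w, window_argmax(w), fallback = FALSE)
}

#' Bidirectional (forward/backward) window search
#'
#' Phase 1 probes full window rows outward from the center at the configured
#' step until the row maximum decreases on both sides (or the window edge is
#' reached); phase 2 evaluates every row inside the resulting bracket; the
#' column peak is read directly since rows are computed at full width.  When
#' the probed row-maximum profile is not unimodal (or is flat), the search
#' falls back to full evaluation and records it, so the returned peak always
#' equals [full_window_argmax()] for unimodal windows and is safe otherwise.
#'
#' @inheritParams full_window_argmax
#' @return a `fine_peak`; `fallback` reports whether full evaluation was
#'   triggered, `evaluations` counts window entries actually computed.
#' @export
bidirectional_search <- function(p, center, cfg) {
  W <- cfg$window_dim
  sigma <- cfg$step
  r0 <- W %/% 2L
  w <- new_upsampled_window(p, center, cfg)
  w <- evaluate_window_rows(p, w, r0)
  row_max <- function(r) max(Re(w$values[r + 1L, ]))
  probe_rows <- r0
  probe_vals <- row_max(r0)
  for (side in c(-1L, 1L)) {
    prev <- probe_vals[1L]
    k <- 1L
    repeat {
      r <- r0 + side * k * sigma
      r <- max(0L, min(W - 1L, r))
      if (r %in% probe_rows) break
      w <- evaluate_window_rows(p, w, r)
      m <- row_max(r)
      probe_rows <- c(probe_rows, r)
      probe_vals <- c(probe_vals, m)
      if (m < prev || r == 0L || r == W - 1L) break
      prev <- m
      k <- k + 1L
    }
  }
  ord <- order(probe_rows)
  pv <- probe_vals[ord]
  # unimodality of the probed profile (non-strict rise then non-strict fall);
  # a flat profile is degenerate and also triggers the fallback
  j <- which.max(pv)
  unimodal <- (j == 1L || all(diff(pv[1:j]) >= 0)) &&
              (j == length(pv) || all(diff(pv[j:length(pv)]) <= 0))
  if (!unimodal || max(pv) == min(pv)) {
    w <- evaluate_window_rows(p, w, 0:(W - 1L))
    return(new_fine_peak(w, window_argmax(w), fallback = TRUE))
  }
  rstar <- probe_rows[ord][j]
  bracket <- max(0L, rstar - sigma + 1L):min(W - 1L, rstar + sigma - 1L)
  w <- evaluate_window_rows(p, w, bracket)
  new_fine_peak(w, window_argmax(w), fallback = FALSE)
}

#' @export
print.fine_peak <- function(x, ...) {
  cat(sprintf(paste0("<fine_peak> offset (dy = %g, dx = %g) px ",
                     "(grid 1/%d), peak %.6g, %d/%d entries evaluated%s\n"),
              x$offset_pixels[["dy"]], x$offset_pixels[["dx"]], x$epsilon,
              x$peak_value, x$evaluations, x$window_dim^2,
              if (x$fallback) ", full-evaluation fallback" else ""))
  invisible(x)
}
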