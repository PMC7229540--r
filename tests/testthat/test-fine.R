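small_bandlimited <- function(M, seed, frac = 0.25) {
  x <- rand_image(M, seed = seed)
  f <- stats::fft(x)
  u <- signed_freq_oracle(M)
  f[!outer(abs(u) <= frac * M / 2, abs(u) <= frac * M / 2)] <- 0
  Re(stats::fft(f, inverse = TRUE)) / (M * M)
}

cps_of_pair <- function(M, truth, seed = 1, smoothness = 0.25,
                        normalized = TRUE) {
  ph <- if (M >= 32) make_phantom(M, seed, smoothness)
        else small_bandlimited(M, seed, smoothness)
  mov <- apply_shift(ph, truth)
  cross_power_spectrum(forward_spectrum(ph), forward_spectrum(mov),
                       normalized = normalized)
}

test_that("DFT row factor: zero lag, conjugate symmetry, epsilon = 1 reduction", {
  cfg <- upsample_config(2L)                       # W = 3, lags center + {-1,0,1}/2
  A <- dft_row_factor(cfg, 0, 16)
  expect_lt(max(Mod(A[2, ] - 1)), 1e-12)           # zero-lag row is all ones
  expect_lt(max(Mod(A[1, ] - Conj(A[3, ]))), 1e-12)  # +/- lag rows conjugate

  # epsilon = 1, integer lags: three-matrix product = ordinary correlation
  p <- cps_of_pair(16, c(2, -3), seed = 21)
  cfg1 <- upsample_config(1L, window_span = 3)     # W = 3, integer lag grid
  w <- evaluate_window_rows(p, new_upsampled_window(p, c(2, -3), cfg1), 0:2)
  surf <- correlation_surface(p)$values * 256      # unnormalized scale
  for (r in 0:2) for (cc in 0:2) {
    lag <- c(2, -3) + c(r - 1, cc - 1)
    expect_lt(abs(Re(w$values[r + 1, cc + 1]) -
                  surf[lag[1] %% 16 + 1, lag[2] %% 16 + 1]), 1e-8)
  }
  expect_error(dft_row_factor(cfg, 0, 16, rows = 5), "out of range")
})

test_that("single-point upsampled values are consistent with the FFT surface", {
  x <- rand_image(12, seed = 22)
  s1 <- forward_spectrum(x)
  p <- cross_power_spectrum(s1, s1, normalized = TRUE)
  # identical images, zero lag: all magnitudes 1, so the sum is M1*M2
  expect_equal(Re(upsampled_value(p, 0, 0)), 144, tolerance = 1e-9)
  expect_lt(abs(Im(upsampled_value(p, 0, 0))), 1e-9)

  # at integer lags the single-point sum equals the transform surface
  p2 <- cps_of_pair(16, c(4, -2), seed = 23, normalized = FALSE)
  surf <- correlation_surface(p2)$values * 256
  for (lag in list(c(0, 0), c(4, 14), c(13, 3))) {
    expect_lt(abs(Re(upsampled_value(p2, lag[1], lag[2])) -
                  surf[lag[1] + 1, lag[2] + 1]), 1e-6)
  }

  # on the epsilon-grid it equals the zero-padded upsampled surface
  eps <- 4
  oracle <- zeropad_surface_oracle(p2$values, eps)
  for (rc in list(c(3, 5), c(17, 2), c(60, 63))) {
    expect_lt(abs(Re(upsampled_value(p2, rc[1] / eps, rc[2] / eps)) -
                  oracle[rc[1] + 1, rc[2] + 1]) / max(abs(oracle)), 1e-10)
  }
})

test_that("lazy row evaluation is complete, idempotent and oracle-exact", {
  p <- cps_of_pair(24, c(1.3, -0.6), seed = 24)
  cfg <- upsample_config(4L)                       # W = 6
  W <- cfg$window_dim
  center <- c(1, -1)

  w <- new_upsampled_window(p, center, cfg)
  w <- evaluate_window_rows(p, w, 0:(W - 1))
  # one-shot three-matrix product A * P * C
  A <- dft_row_factor(cfg, center[1], 24)
  C <- t(dft_row_factor(cfg, center[2], 24))
  full <- A %*% p$values %*% C
  expect_lt(max(Mod(w$values - full)), 1e-10)
  expect_identical(w$evaluations, W * W)

  # re-requesting rows changes nothing
  w2 <- evaluate_window_rows(p, w, c(0, 3))
  expect_identical(w2$values, w$values)
  expect_identical(w2$evaluations, w$evaluations)

  # each row matches the zero-padded FFT oracle at the same lags
  oracle <- zeropad_surface_oracle(p$values, cfg$epsilon)
  scale <- max(abs(oracle))
  for (r in 0:(W - 1)) {
    for (cc in c(0, 2, W - 1)) {
      ridx <- (cfg$epsilon * center[1] + r - W %/% 2) %% (cfg$epsilon * 24)
      cidx <- (cfg$epsilon * center[2] + cc - W %/% 2) %% (cfg$epsilon * 24)
      expect_lt(abs(Re(w$values[r + 1, cc + 1]) - oracle[ridx + 1, cidx + 1]) / scale,
                1e-8)
    }
  }
})

test_that("full window argmax equals the zero-padding oracle block", {
  p <- cps_of_pair(24, c(2.3, -1.7), seed = 25)
  cfg <- upsample_config(8L)                       # W = 12
  fp <- full_window_argmax(p, c(2, -2), cfg)
  expect_equal(fp$evaluations, cfg$window_dim^2)
  expect_false(fp$fallback)

  oracle <- zeropad_surface_oracle(p$values, 8)
  # global oracle argmax, mapped into window coordinates
  best <- which(oracle == max(oracle), arr.ind = TRUE)[1, ] - 1
  est <- c(2, -2) + fp$offset_pixels
  wrapped <- c(wrap_shift(best[1], 8 * 24), wrap_shift(best[2], 8 * 24)) / 8
  expect_equal(unname(est), unname(wrapped), tolerance = 1e-12)
})

test_that("bidirectional search reproduces the full argmax with fewer evaluations", {
  # peak exactly at the window center
  p <- cps_of_pair(32, c(3, 4), seed = 26)
  cfg <- upsample_config(10L)
  fp <- bidirectional_search(p, c(3, 4), cfg)
  expect_equal(unname(fp$offset_pixels), c(0, 0))
  expect_lt(fp$evaluations, cfg$window_dim^2)

  # property: agreement with the full window over seeded fractional cases
  set.seed(77)
  n_agree <- 0L
  for (i in 1:25) {
    truth <- runif(2, -0.45, 0.45)
    p <- cps_of_pair(32, truth, seed = 300 + i)
    fb <- bidirectional_search(p, c(0, 0), cfg)
    ff <- full_window_argmax(p, c(0, 0), cfg)
    if (identical(fb$offset_upsampled, ff$offset_upsampled)) n_agree <- n_agree + 1L
    expect_lte(fb$evaluations, cfg$window_dim^2)
  }
  expect_gte(n_agree, 24L)
})

test_that("fine stage resolves a fractional shift to 0.01 px at epsilon = 100", {
  truth <- c(0.34, -0.27)
  p <- cps_of_pair(64, truth, seed = 27)
  fp <- bidirectional_search(p, c(0, 0), upsample_config(100L))
  expect_lt(max(abs(fp$offset_pixels - truth)), 0.01 + 1e-12)
})

test_that("combined estimates are quantized to the upsampling grid", {
  truth <- c(-2.437, 3.591)
  ph <- make_phantom(64, 28)
  case <- make_shifted_pair(ph, truth)
  for (eps in c(10L, 100L, 1000L)) {
    res <- register_translation(case$reference, case$moving,
                                registration_config(upsample = upsample_config(eps)))
    expect_lt(max(abs(res$shift - truth)), 1 / eps + 1e-6)
  }
})

test_that("degenerate windows fall back to full evaluation", {
  # an identically zero cross spectrum gives a flat (all-zero) window; the
  # search cannot bracket anything and must record a full-evaluation fallback
  p <- cross_power_spectrum(matrix(0 + 0i, 16, 16), matrix(0 + 0i, 16, 16),
                            normalized = TRUE)
  fp <- bidirectional_search(p, c(7, 7), upsample_config(4L))
  expect_true(fp$fallback)
  expect_equal(fp$evaluations, fp$window_dim^2)
})
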