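make_pair_spectra <- function(M, truth, seed = 1, smoothness = 0.25) {
  ph <- make_phantom(M, seed, smoothness)
  case <- make_shifted_pair(ph, truth)
  list(s1 = forward_spectrum(case$reference),
       s2 = forward_spectrum(case$moving))
}

test_that("spectrum decimation selects the comb and refuses unsafe input", {
  x <- rand_image(8, seed = 2)
  p <- cross_power_spectrum(forward_spectrum(x),
                            forward_spectrum(roll2(x, 1, 1)), normalized = TRUE)

  # K = 1 is the identity
  pd <- decimate_cross_spectrum(p, downsample_config(1L))
  expect_identical(pd$values, p$values)

  # K = 2 keeps indices 0, 2, 4, 6 on both axes (DC always retained)
  pd <- decimate_cross_spectrum(p, downsample_config(2L))
  expect_identical(dim(pd$values), c(4L, 4L))
  expect_identical(pd$values, p$values[c(1, 3, 5, 7), c(1, 3, 5, 7)])

  expect_error(decimate_cross_spectrum(p, downsample_config(3L)),
               "nearest divisor")
  pun <- cross_power_spectrum(forward_spectrum(x),
                              forward_spectrum(roll2(x, 1, 1)), normalized = FALSE)
  expect_error(decimate_cross_spectrum(pun, downsample_config(2L)),
               "normalize")
})

test_that("decimated surface is the sum of aliased replicas of the full surface", {
  f1 <- rand_image(12, seed = 31)
  f2 <- roll2(f1, 2, 1) + 0.05 * rand_image(12, seed = 32)
  p <- cross_power_spectrum(forward_spectrum(f1), forward_spectrum(f2),
                            normalized = TRUE)
  full <- correlation_surface(p)$values
  pd <- decimate_cross_spectrum(p, downsample_config(2L, 3L, auto = FALSE))
  small <- correlation_surface(pd)$values
  m <- dim(small)
  for (r in 0:(m[1] - 1)) for (cc in 0:(m[2] - 1)) {
    replicas <- outer(r + m[1] * 0:1, cc + m[2] * 0:2,
                      function(a, b) full[a %% 12 + 1 + 12 * (b %% 12)])
    expect_lt(abs(small[r + 1, cc + 1] - sum(replicas)), 1e-8)
  }
})

test_that("the auto rule picks K = M/32 with a divisor fallback", {
  expect_identical(subshift:::auto_decimation(256L), 8L)
  expect_identical(subshift:::auto_decimation(512L), 16L)
  expect_identical(subshift:::auto_decimation(64L), 2L)
  expect_identical(subshift:::auto_decimation(48L), 1L)   # 48/32 not integral
  expect_identical(subshift:::auto_decimation(96L), 3L)
})

test_that("decimated coarse estimates match the full-resolution peak inside the bound", {
  sp <- make_pair_spectra(128, c(0, 0), seed = 7)
  est <- coarse_shift_decimated(sp$s1, sp$s2, downsample_config(4L))
  expect_true(est$valid)
  expect_equal(unname(est$shift), c(0, 0))

  sp <- make_pair_spectra(128, c(5, 7), seed = 8)
  est <- coarse_shift_decimated(sp$s1, sp$s2, downsample_config(4L))
  expect_true(est$valid)
  expect_equal(unname(est$shift), c(5, 7))
  full <- locate_integer_peak(correlation_surface(
    cross_power_spectrum(sp$s1, sp$s2, normalized = TRUE)))
  expect_equal(est$shift, full$shift)

  # property: random shifts inside |d| < M/(2K) - 1, several K
  set.seed(1234)
  for (K in c(2L, 4L, 8L)) {
    bound <- 128 %/% (2L * K) - 2L
    for (i in 1:5) {
      d <- sample(-bound:bound, 2, replace = TRUE)
      sp <- make_pair_spectra(128, d, seed = 100 * K + i)
      est <- coarse_shift_decimated(sp$s1, sp$s2, downsample_config(K))
      expect_true(est$valid)
      expect_equal(unname(est$shift), d)
    }
  }
})

test_that("out-of-bound shifts are flagged ambiguous and disambiguated", {
  # M = 128, K = 4: aliasing period 32, bound |d| < 15; true shift 40 = 8 + 32
  sp <- make_pair_spectra(128, c(40, 0), seed = 9)
  est <- coarse_shift_decimated(sp$s1, sp$s2, downsample_config(4L))
  expect_true(est$ambiguous)
  expect_equal(unname(est$shift), c(8, 0))   # wrapped alias of the true 40
  dys <- est$candidates[, "dy"]
  expect_true(all(c(8, 40, -24, -56) %in% dys))
  expect_true(all(dys %% 32 == 8 | dys %% 32 == 8 - 32))

  fixed <- disambiguate_candidates(sp$s1, sp$s2, est)
  expect_true(fixed$valid)
  expect_false(fixed$ambiguous)
  expect_equal(unname(fixed$shift), c(40, 0))

  # single candidate passes through unchanged
  est1 <- est
  est1$candidates <- est$candidates[est$candidates[, "dy"] == 40 &
                                    est$candidates[, "dx"] == 0, , drop = FALSE]
  out <- disambiguate_candidates(sp$s1, sp$s2, est1)
  expect_true(out$valid)
  expect_equal(unname(out$shift), c(40, 0))

  est0 <- est
  est0$candidates <- est$candidates[0, , drop = FALSE]
  expect_error(disambiguate_candidates(sp$s1, sp$s2, est0), "no candidates")
})

test_that("baseline factor-2 coarse stage reaches half-pixel accuracy", {
  # integer shift: exact recovery
  sp <- make_pair_spectra(64, c(3, 5), seed = 10)
  est <- coarse_shift_baseline(sp$s1, sp$s2)
  expect_equal(unname(est$shift), c(3, 5), tolerance = 1e-12)

  # fractional shift: within half a pixel per axis
  sp <- make_pair_spectra(64, c(3.5, -2.5), seed = 11)
  est <- coarse_shift_baseline(sp$s1, sp$s2)
  expect_lt(max(abs(est$shift - c(3.5, -2.5))), 0.5 + 1e-9)

  # the padded surface is the global epsilon = 2 upsampled correlation:
  # every half-pixel lag matches the single-point exponential sum
  x <- rand_image(12, seed = 12)
  y <- roll2(x, 2, -3)
  s1 <- forward_spectrum(x); s2 <- forward_spectrum(y)
  p <- cross_power_spectrum(s1, s2, normalized = TRUE)
  oracle <- zeropad_surface_oracle(p$values, 2) / length(x)
  for (r in c(0, 5, 13, 23)) for (cc in c(0, 7, 20)) {
    direct <- Re(upsampled_value(p, r / 2, cc / 2)) / length(x)
    expect_lt(abs(direct - oracle[r + 1, cc + 1]), 1e-8)
  }
})

test_that("decimated coarse estimates tolerate 10 dB additive noise", {
  n_ok <- 0L
  n_trials <- 30L
  for (i in seq_len(n_trials)) {
    ph <- make_phantom(64, 500 + i)
    d <- c((i %% 11) - 5, ((3 * i) %% 11) - 5)
    # 10 dB SNR: noise sd = signal sd / sqrt(10), expressed vs dynamic range
    sigma <- stats::sd(ph) / sqrt(10) / diff(range(ph))
    noisy <- make_shifted_pair(ph, d, noise_sigma = sigma, seed = 700 + i)
    est <- coarse_shift_decimated(forward_spectrum(noisy$reference),
                                  forward_spectrum(noisy$moving),
                                  downsample_config(2L))
    if (est$valid && all(est$shift == d)) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, ceiling(0.95 * n_trials))
})
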