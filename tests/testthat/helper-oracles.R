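# Brute-force oracles, written independently of the package's code paths.
# All loops are plain O(N^4) sums; only usable on small fixtures.

# forward 2-D DFT by direct double summation, kernel exp(-2i*pi*(ur/M1 + vc/M2))
dft2_brute <- function(x) {
  M1 <- nrow(x); M2 <- ncol(x)
  out <- matrix(0 + 0i, M1, M2)
  for (u in 0:(M1 - 1)) for (v in 0:(M2 - 1)) {
    s <- 0 + 0i
    for (r in 0:(M1 - 1)) for (cc in 0:(M2 - 1))
      s <- s + x[r + 1, cc + 1] * exp(-2i * pi * (u * r / M1 + v * cc / M2))
    out[u + 1, v + 1] <- s
  }
  out
}

# circular cross-correlation S(dy, dx) = sum_x f1(x) * f2(x + d) by direct sum
circ_xcorr_brute <- function(f1, f2) {
  M1 <- nrow(f1); M2 <- ncol(f1)
  out <- matrix(0, M1, M2)
  for (dy in 0:(M1 - 1)) for (dx in 0:(M2 - 1)) {
    s <- 0
    for (r in 0:(M1 - 1)) for (cc in 0:(M2 - 1))
      s <- s + f1[r + 1, cc + 1] *
        f2[((r + dy) %% M1) + 1, ((cc + dx) %% M2) + 1]
    out[dy + 1, dx + 1] <- s
  }
  out
}

# circular integer roll: out(r, c) = x(r - dy, c - dx), i.e. x shifted by +d
roll2 <- function(x, dy, dx) {
  M1 <- nrow(x); M2 <- ncol(x)
  x[((0:(M1 - 1) - dy) %% M1) + 1, ((0:(M2 - 1) - dx) %% M2) + 1]
}

signed_freq_oracle <- function(M) {
  u <- 0:(M - 1)
  ifelse(u <= M / 2, u, u - M)
}

# upsampled correlation by signed-frequency zero padding: entry (r, c)
# (0-based) is the unnormalized correlation at lag (r/factor, c/factor)
zeropad_surface_oracle <- function(pvals, factor) {
  M1 <- nrow(pvals); M2 <- ncol(pvals)
  big <- matrix(0 + 0i, factor * M1, factor * M2)
  rows <- (signed_freq_oracle(M1) %% (factor * M1)) + 1
  cols <- (signed_freq_oracle(M2) %% (factor * M2)) + 1
  big[rows, cols] <- pvals
  Re(stats::fft(big))
}

rand_image <- function(M1, M2 = M1, seed = 1) {
  set.seed(seed)
  matrix(rnorm(M1 * M2), M1, M2)
}
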