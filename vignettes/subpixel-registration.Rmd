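---
title: "Subpixel translation registration by decimated phase correlation and single-step DFT upsampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subpixel translation registration by decimated phase correlation and single-step DFT upsampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subshift)
```

## Model and assumptions

`subshift` estimates a rigid translation between two same-size 2-D
grayscale images under a *circular* (periodic) image model:

\[ f_2(r, c) = f_1((r - d_y) \bmod M_1,\; (c - d_x) \bmod M_2). \]

Everything in the package commits to this one convention: the moving image
is the reference translated by \(+(d_y, d_x)\), rows first, 0-based. The
assumptions the method inherits from phase correlation are:

* the geometric relation is a pure translation (no rotation, scaling, or
  local deformation);
* the images share enough spectral content that the cross-power phase is
  informative (they need not share intensity calibration — normalization
  discards magnitudes, and the NRMSE metric optimizes out a global scale);
* boundaries behave periodically. Real images are not periodic; for pairs
  with large shifts and strong edge content, windowing or cropping before
  registration is the user's responsibility.

By the shift theorem the normalized cross-power spectrum of such a pair is
the phase ramp \(\exp(+2\pi i(u d_y/M_1 + v d_x/M_2))\), whose correlation
surface is a unit impulse at \((d_y, d_x)\). The estimator localizes that
impulse, first at pixel and then at subpixel resolution.

### Transform conventions

The forward transform is the unnormalized DFT with kernel
\(e^{-2\pi i(ur/M_1+vc/M_2)}\) in machine frequency order (`stats::fft`),
and the correlation surface is computed with the *same* kernel scaled by
\(1/(M_1 M_2)\), which makes it equal to the circular cross-correlation
\(\sum_x f_1(x) f_2(x+d)\) and puts the peak at \(+d\) rather than \(-d\).
Sign conventions differ across registration tools; fixing one and testing
it end-to-end (generator → estimator → metrics) removes the single most
common integration bug. Peak indices \(p \in [0, M)\) map to signed shifts
via \(p \mapsto p\) if \(p \le M/2\), else \(p - M\), so shifts live in
\((-M/2, M/2]\) with the boundary on the positive side.

## Coarse stage: spectral decimation

Inverting the full cross spectrum costs an \(M_1 \times M_2\) FFT per pair.
The coarse stage instead keeps every \(K\)-th spectral sample per axis
(always including DC) and inverts only an \((M_1/K_1) \times (M_2/K_2)\)
matrix. Frequency-domain sampling aliases the spatial domain: the small
surface is exactly the sum of the \(K_1 K_2\) periodic replicas of the full
surface with period \((M_1/K_1, M_2/K_2)\) — an identity the test suite
checks by brute force. Two consequences drive the design:

* **Normalization is mandatory before decimation.** For an unnormalized
  spectrum the replicas carry image-dependent magnitudes and their overlap
  can move the argmax; for the normalized spectrum the surface is (near) a
  delta, so replicas are well separated and the peak survives wherever it
  lands inside the decimated frame. `decimate_cross_spectrum` therefore
  refuses unnormalized input.
* **The peak is only known modulo \(M/K\).** A decimated peak at \(\tilde d\)
  is consistent with every shift \(\tilde d + j\,M/K\). The estimate is
  marked `valid` when the wrapped peak is unique and lies strictly inside
  the conservative bound \(|\tilde d| < M/(2K) - 1\) — half the aliasing
  period, not the full period, because beyond half the period the wrapped
  *sign* is itself ambiguous. Whenever aliases exist, the full candidate
  grid (at most \(K_1 K_2\) shifts) is attached; `disambiguate_candidates`
  evaluates the full-resolution unnormalized correlation at each candidate
  by a direct exponential-weighted sum (one \(O(M_1 M_2)\) dot product per
  candidate, no global inverse FFT) and keeps the largest real value. The
  pipeline runs this step only when the estimate is not `valid`; callers
  whose shifts may exceed the bound can run it unconditionally.

The default decimation follows the rule \(K = M/32\) per axis (decimated
frame 32 × 32) when \(M \ge 64\) and \(32 \mid M\); otherwise the largest
divisor of \(M\) leaving at least 32 samples. A minimum decimated extent of
4 samples per axis is enforced.

## Fine stage: single-step DFT window

The subpixel refinement evaluates the upsampled correlation only on a
\(W \times W\) window of lags centred on the coarse estimate, with
\(W = \lceil 1.5\,\varepsilon\rceil\) and grid step \(1/\varepsilon\) px.
Window sample \(r\) maps to lag \(\text{center} + (r - \lfloor W/2\rfloor)/
\varepsilon\), which keeps zero lag exactly on the grid for every
\(\varepsilon\) (for \(\varepsilon\) divisible by 4 this coincides with a
window spanning \([-0.75, +0.75]\) px). The window is the three-matrix
product

\[ R = A_{W\times M_1}\; P_{M_1\times M_2}\; C_{M_2\times W},\qquad
   A_{r,u} = e^{-2\pi i\, d_y(r)\, u'/M_1}, \]

with \(u'\) the signed frequency. This is algebraically identical to the
corresponding block of the \(\varepsilon\)-factor zero-padded inverse FFT
(the test suite asserts agreement to \(10^{-8}\) relative over many seeded
spectra) but costs \(O(W M_1 M_2 + W^2 M_2)\) instead of
\(O(\varepsilon^2 M_1 M_2 \log(\cdot))\) and needs no
\(\varepsilon M_1 \times \varepsilon M_2\) array.

Two exact optimizations matter in practice:

* **Row-lazy factorization.** \(D = P\,C\) is computed once; each window
  row is then a single vector–matrix product \(A_r D\). Rows are always
  full width, so once the best row is known the column argmax is read
  directly.
* **Zero pruning.** All-zero rows/columns of \(P\) (band-limited content,
  or entries zeroed by the magnitude floor) contribute nothing to the
  product and are dropped. This is exact algebra, not an approximation.

### Bidirectional search

A full window costs \(W^2\) evaluated entries. Because the upsampled
correlation peak is locally unimodal (parabola-like) for well-behaved
content, the search probes rows outward from the window centre at step
\(\sigma = \max(1, \operatorname{round}(0.3\,\varepsilon))\) until the row
maximum decreases on both sides, then evaluates every row inside the
bracket \((r^* - \sigma, r^* + \sigma)\). If the probed row-maximum profile
is unimodal this returns exactly the full-window argmax; if it is not (or
is flat), the search falls back to full evaluation and records the fact.
On the standard fixtures the search evaluates ~40 % of the window. The peak
criterion is the maximum of the *real part* (the imaginary residue of these
windows is at rounding level for real images); ties break to the smallest
row-major index, everywhere, for determinism.

The combined estimate is \(d = \text{coarse} + \text{offset}/\varepsilon\),
so the attainable accuracy is the grid quantization \(1/(2\varepsilon)\)
per axis — e.g. at most 0.005 px at \(\varepsilon = 100\). A claim of
0.001-px accuracy at \(\varepsilon = 100\) is not attainable on a 1/100
grid and is deliberately not targeted.

### Baseline method

The reference two-step algorithm is included both as a scientific baseline
and as an internal cross-check: a global factor-2 zero-padded correlation
(half-pixel resolution, embedding the spectrum at its signed frequencies),
rounding to the nearest integer (half away from zero), then the *full*
fine window. Its fine stage shares no search logic with the improved
method, which makes the agreement property (within \(1/\varepsilon\) per
axis on clean fixtures) a meaningful test.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `epsilon` | 100 | – | fine grid is `1/epsilon` px; error floor `1/(2 epsilon)` |
| `window_span` | 1.5 | px | fine window side; covers the ≤ 0.75 px coarse residual |
| `step_fraction` | 0.3 | – | probe step `sigma = max(1, round(0.3 epsilon))` grid units |
| `k1`, `k2` (auto) | `M/32` | – | decimation; validity bound `M/(2K) − 1` px |
| `magnitude_floor` | `1e-12 · max` | – | spectral zeros are set to 0, not divided |
| `normalized_spectrum` | `TRUE` | – | pure-phase correlation in all stages |

The magnitude floor exists because normalization divides by
\(|F_1 F_2^*|\), which is undefined at exact spectral zeros (common in
synthetic band-limited images); floored entries are excluded rather than
amplified, and the zero pruning then removes them from the fine products.

## The synthetic generator, and what passing tests show

`make_phantom` draws a seeded Gaussian random field and hard low-pass
filters it to \(|f| \le \text{smoothness}\cdot\) Nyquist per axis
(default smoothness 0.25), rescaling to exactly \([0, 1]\).
`make_shifted_pair` translates it by the exact spectral phase ramp and
optionally adds seeded Gaussian noise scaled by the dynamic range. Two
properties make this a *calibrated* benchmark:

* a band-limited image has no Nyquist energy, so the fractional Fourier
  shift is exact and real — the ground truth carries no interpolation
  error, and every benchmark error is attributable to the estimator;
* shifts are applied circularly, matching the estimator's image model, so
  boundary effects do not contaminate the error attribution.

This is also what the generator does **not** emulate: real scanner pairs
are not circularly periodic, are not band-limited, have structured rather
than white-noise content, and multimodal pairs (PET vs CT) have nonlinear
intensity relationships. Passing the benchmark demonstrates the estimator's
correctness and its quantization/noise behaviour under its own model; it
does not certify performance on clinical data. The noise robustness
properties (estimates within \(5/\varepsilon\) px under 5 %-of-range noise;
coarse estimates stable at 10 dB SNR) are package-level thresholds chosen
to exercise the claim of noise insensitivity, not published figures.

For the Nyquist bin of even-sized images, `apply_shift` replaces the ramp
value \(e^{-i\pi d}\) by \(\cos(\pi d)\), keeping the shifted spectrum
Hermitian so real images stay exactly real; this coincides with the exact
ramp at integer shifts and is irrelevant for band-limited content.

## Problem sizes used in the checks

The accuracy protocol registers 20 pairs generated from one 256 × 256
phantom with per-axis shifts uniform in ±10 px (decimated coarse frame
32 × 32): the maximum per-axis error at \(\varepsilon = 100\) and the mean
per-axis errors of both methods at \(\varepsilon = 2000\). Peak
preservation under decimation is exercised with 50 in-bound integer shifts
for each \(K \in \{2, 4, 8, 16\}\) at \(M = 128\); search admissibility
with 200 seeded 64 × 64 fixtures at \(\varepsilon = 100\); the
window-vs-zero-padding equivalence with 50 seeded spectra at \(M \le 32\),
\(\varepsilon \le 8\). Brute-force \(O(N^4)\) oracles (direct DFT sums and
direct circular correlation) back the spectral core on instances up to
12 × 12. These sizes were chosen so the full suite runs in well under a
minute while every claim is still exercised at its native scale.

## Numerical choices and degenerate inputs

* Ties in any argmax resolve to the smallest row-major index; candidate
  ties in disambiguation resolve to the smallest (dy, dx) lexicographically
  and are reported.
* Constant images are rejected up front (no registrable structure), as are
  non-finite pixels (with the offending index named).
* A flat or multi-modal probed profile in the bidirectional search forces
  the recorded full-evaluation fallback rather than a silent wrong bracket.
* Imaginary residues of inverse transforms are asserted small relative to
  the signal before the real part is taken.
* Baseline coarse estimates at exactly half-pixel positions round half away
  from zero, so the window centre never depends on floating-point parity
  quirks; the 1.5-px window covers the worst-case 0.75 px residual either
  way.
* When a coarse estimate sits within a pixel of \(\pm M/2\), window lags
  simply wrap circularly — the lag enters the exponentials directly, so no
  special casing is needed.

## Known limitations

* Translation only: rotation, scaling and nonrigid deformation are out of
  scope (a log-polar or feature-based front end would be needed).
* The circular model means content entering or leaving the frame violates
  the assumptions; accuracy on real cropped pairs degrades with shift size.
* The decimated coarse stage is blind to shifts beyond half its aliasing
  period unless disambiguation is invoked; with the default K = M/32 the
  validity bound is `M/(2K) − 1 = 15` px regardless of image size.  Larger
  expected shifts call for a smaller K (or unconditional disambiguation).
* Accuracy is floored at the fine-grid quantization \(1/(2\varepsilon)\);
  there is no sub-grid interpolation below \(1/\varepsilon\) by design.
* 2-D only; no DICOM/NIfTI readers (convert to TIFF first).
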