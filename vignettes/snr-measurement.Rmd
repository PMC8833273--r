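---
title: "Measuring MR image SNR from fully attenuated noise images"
author: "combetSNR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring MR image SNR from fully attenuated noise images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combetSNR)
```

## The measurement problem

The signal-to-noise ratio of a magnitude MR image is the mean signal
intensity in a region of interest divided by the noise standard
deviation. The signal part is easy; the noise part is not, because a
magnitude image contains no pixels that are "just noise" with the naive
Gaussian statistics one would like:

* background ROIs outside the object are biased by the magnitude
  operation and become unusable when parallel imaging or intensity
  normalisation makes the noise spatially varying;
* the subtraction method — two identical scans, noise from the SD of
  their difference divided by √2 — is the accepted reference for
  phantoms, but needs two registered, drift-free acquisitions, which
  in-vivo imaging rarely provides.

This package implements the noise-image family of estimators: acquire a
second image with the *same* sequence but with acquisition parameters
chosen so that the object signal itself decays below the digitisation
floor, leaving a pure-noise image in perfect geometric register with the
signal image. Two variants are distinguished only by how the noise image
is attenuated:

* **maximum b-value + longest TE** (`method = "combet"`): diffusion
  weighting and T2 decay multiply, so even extremely long-T2 media
  (purified water, CSF, digestive fluid) are suppressed;
* **longest TE only** (`method = "delset"`): works only when the longest
  available TE is roughly eight times the material's T2; for water at
  T2 = 2390 ms and TE = 500 ms the noise image retains
  exp(−500/2390) ≈ 81 % of the T2-weighted signal, which inflates the
  noise estimate and biases the SNR low. The package reproduces this
  failure mode, which is the motivation for the combined acquisition.

How complete is the attenuation in the combined case?
`residualSignalFraction(te, t2, b, d)` returns
exp(−TE/T2 − b·D), the residual as a fraction of the TE = 0, b = 0
signal. For water at TE = 500 ms, b = 18000 s/mm², the fraction is
3.11×10⁻¹⁷; at TE = 275 ms it is 3.42×10⁻¹⁷. Both are some twelve orders
of magnitude below the signed 16-bit quantization floor
(`quantizationFloorPercent(16)` = 100/32768 ≈ 3.1×10⁻³ per cent), so the
recorded noise image is signal-free by construction. The T1 saturation
factor is deliberately left out of this quantity: it is common to the
TE = 0 reference and the noise image and cancels in the ratio.

## Noise statistics of sum-of-squares reconstruction

With N coil channels, each contributing independent Gaussian noise of SD
σ to its real and imaginary components, a signal-free pixel of the
root-sum-of-squares magnitude image is σ times a central chi variate
with 2N degrees of freedom. Its mean is σ·β(N) with

β(N) = √(π/2) · (2N−1)!! / (2^(N−1) (N−1)!) = √2 · Γ(N+½) / Γ(N),

and its SD is σ·√(2N − β(N)²). `correctSD()` therefore divides the
measured noise-image SD by `sdCorrectionDivisor(N)` = √(2N − β(N)²) to
recover the per-channel σ, and the SNR is the ROI mean of the signal
image over that corrected SD.

Numerical choices:

* β(N) is evaluated in log space via
  log((2N−1)!!) = lgamma(2N) − (N−1)·log 2 − lgamma(N); naive factorials
  overflow double precision near N ≈ 90 and lose accuracy much earlier.
  The gamma-function closed form is kept as an independent cross-check
  in the test suite (agreement to better than 10⁻¹⁰ for N ≤ 64).
* all SDs are sample SDs (n−1 denominator). With the conventional
  52-pixel ROIs the n vs n−1 choice shifts the noise estimate by about
  1 %, so it must be fixed; the unbiased-variance convention is the
  standard one in QA practice.
* a measured noise SD of exactly zero raises an error rather than
  returning an infinite SNR: an all-constant noise image means a broken
  acquisition or a wrong file, which QA software must surface.
* the subtraction estimator pools the ROI mean over both repeats
  (symmetric in the two images) and applies the √2 correction to the
  difference SD. Its correction does not depend on N.

## Regions of interest and maps

Published ROI sizes are pixel counts (52 pixels for the five-ROI layout,
1264 for the large central ROI), not radii. `circularROI()` therefore
resolves to **exactly** the requested number of pixels: the grid pixels
nearest the center in Euclidean distance, ties broken deterministically
in row-major order. This makes ROI statistics reproducible to the pixel
across runs and machines. Explicit masks are supported for irregular
regions.

`slidingWindowMaps()` computes the local signal mean, corrected noise SD
and their ratio in a square window (default 7×7, the conventional
choice) around every pixel. Border pixels whose window leaves the image
are flagged invalid rather than padded — padding would fabricate noise
statistics. Each interior map pixel equals exactly what the ROI
estimator returns on that pixel's window, which the tests assert
pixel-by-pixel.

One caveat when reading noise maps: a 49-pixel sample SD has a relative
sampling error of about √((κ−1)/(4·49)) ≈ 10 % (κ the kurtosis of the
chi distribution), so even a perfectly uniform noise field produces a
map whose extremes over thousands of windows span a ratio of roughly
1.8–2. Uniformity should be judged by regional means (e.g. inside the
object versus background), not by the max/min of single windows.

## The acquisition simulator

`simulateScan()` generates the data the estimators are validated
against. Its signal model is the minimal spin-echo steady state
consistent with the method's premises:

S = PD · (1 − e^(−TR/T1)) · e^(−TE/T2) · e^(−b·D),

scaled linearly by slice thickness and a system gain, fed through
per-channel complex coil sensitivities, perturbed by independent
Gaussian noise (SD σ per channel and component) and reconstructed by
root sum of squares; optional signed 16-bit quantization maps the
maximum noiseless TE = 0, b = 0 signal to 32767. Default parameter
choices mirror a 3-T phantom study: water (T1 3505 ms, T2 2390 ms,
D 2.1×10⁻³ mm²/s) and mineral oil (T1 196 ms, T2 75 ms,
D 0.04×10⁻³ mm²/s) discs of 10 cm diameter, 128×128 matrix over a
256-mm field of view, 5-mm slices, TR 3000 ms, TE 37 ms, noise image at
TE 500 ms and b 18000 s/mm², 16 channels (see the bundled configs in
`inst/extdata/`).

Reproducibility: every scan is seeded; series and signal/noise pairs
derive per-image seeds from the master seed by fixed increments, so a
given (phantom, parameters, seed) triple yields bit-identical pixels.

What the simulator deliberately does **not** model: k-space acquisition
and EPI distortion or ghosting, parallel-imaging (SENSE/GRAPPA) noise
amplification, T2\* effects, coil-profile shading (sensitivities default
to 1), fluid convection and inter-scan drift, and 3-D volumes. Isotropic
scalar diffusion makes the three orthogonal gradient directions
equivalent. Passing tests on simulated data therefore demonstrate the
*statistical* correctness of the estimators under the stated noise
model, not robustness to scanner artefacts; on real systems the
subtraction method additionally suffers from exactly the drift and
convection effects the simulator omits.

## Validation design and a known limitation

The estimator tests define the ground truth carefully. With "true SNR"
defined as the noiseless sum-of-squares amplitude divided by σ, the
noise-image estimator actually measures E[M]/σ, where M is a noncentral
chi variate — the magnitude noise floor biases the ROI mean upward. The
bias is negligible at high SNR (+0.15 % at SNR 100, N = 16) but grows
rapidly at low SNR with many channels: at amplitude SNR 5 with 16
channels, E[M]/σ = 7.50 (+50 %), and the subtraction method — whose
noise estimate is the SD of the magnitude, 0.85 σ at that operating
point — reads 8.85. In that regime the two estimators measure genuinely
different quantities and neither recovers the amplitude SNR; this is a
property of sum-of-squares magnitude statistics, not of the
implementation. The property tests therefore validate each estimator
against its analytic measurand (E[M]/σ and E[M]/SD(M), computed from an
independent Monte-Carlo oracle over noncentral chi-squared draws) across
amplitude SNRs 5–100 and N ∈ {1, 4, 16}, and assert mutual agreement and
amplitude-SNR recovery in the high-SNR regime where all definitions
coincide. `expectedMagnitude()` exposes the analytic measurand for
users who want to quantify the bias at their own operating point.

Problem sizes in the test suite were chosen to keep the full run under
half a minute on one core while leaving Monte-Carlo error well below
every asserted tolerance: 10⁶-pixel noise-only images for σ recovery
(3-standard-error criterion), 128×128 phantoms with 1264-pixel ROIs and
4–6 repeats for estimator recovery, 2×10⁵-draw oracles, and 20 simulated
repeats for the coefficient-of-variation check.

## Interfaces

Images travel as single-slice NIfTI-1 files (double precision, so pixel
data round-trip bit-identically) with a JSON sidecar carrying what the
NIfTI header cannot: TE, TR, b-value, channel count, σ, seed, coil
sensitivities and slice thickness (NIfTI drops the through-plane spacing
of a single 2-D slice). The command-line verbs `simulate`, `estimate`,
`map` and `validate` (launcher in `inst/cli/combet.R`) wrap the same
functions; `estimate` demotes a `combet` request to `delset` with a
warning when the noise image's metadata shows b = 0, since the label is
a claim about how the noise image was acquired. Every output records the
seed and a checksum of the resolved configuration.
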