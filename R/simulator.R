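## Acquisition simulator: spin-echo steady state with diffusion weighting,
## per-channel complex Gaussian noise and root-sum-of-squares magnitude
## reconstruction. The signal model is the minimal one consistent with the
## method's premises: PD * (1 - exp(-TR/T1)) * exp(-TE/T2) * exp(-b*D),
## with the amplitude scaling linearly with slice thickness. No k-space,
## EPI-readout or parallel-imaging effects are modelled.

.withSeed <- function(seed, fun) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  fun()
}

#' Steady-state spin-echo signal fraction
#'
#' Relative signal of a tissue under repetition time `tr`, echo time `te`
#' and diffusion weighting `bValue`:
#' `PD * (1 - exp(-TR/T1)) * exp(-TE/T2) * exp(-b*D)`.
#'
#' @param tissue a [TissueProperties-class].
#' @param tr repetition time in ms (> 0).
#' @param te echo time in ms (>= 0).
#' @param bValue diffusion weighting in s/mm^2 (>= 0), default 0.
#' @return dimensionless signal fraction (1 = full proton density with
#'   complete T1 recovery and no decay).
#'
#' @examples
#' water <- TissueProperties(3505, 2390, 2.1e-3)
#' relativeSignal(water, tr = 3000, te = 37)   # about 0.566
#' @seealso [residualSignalFraction()], [simulateScan()]
#' @export
relativeSignal <- function(tissue, tr, te, bValue = 0) {
  stopifnot(is(tissue, "TissueProperties"))
  if (any(tr <= 0)) stop("tr must be > 0", call. = FALSE)
  if (any(te < 0)) stop("te must be >= 0", call. = FALSE)
  if (any(bValue < 0)) stop("bValue must be >= 0", call. = FALSE)
  tissue@protonDensity * (1 - exp(-tr / tissue@t1)) *
    exp(-te / tissue@t2) * exp(-bValue * tissue@d)
}

#' Residual signal of a fully attenuated noise image
#'
#' Theoretical fraction of the TE = 0, b = 0 signal left after T2 decay and
#' diffusion attenuation: `exp(-te/t2) * exp(-bValue * d)`. For a noise
#' image acquired with the maximum b-value and longest TE this should fall
#' below the scanner's quantization floor, so the image contains pure
#' noise. Multiply by 100 for a percentage.
#'
#' @param te echo time in ms (>= 0).
#' @param t2 transverse relaxation time in ms (> 0).
#' @param bValue diffusion weighting in s/mm^2 (>= 0).
#' @param d apparent diffusion coefficient in mm^2/s (>= 0).
#' @return dimensionless residual fraction in `[0, 1]`.
#'
#' @examples
#' ## purified water, maximum b-value and long TE: ~3.1e-17
#' residualSignalFraction(500, 2390, 18000, 2.1e-3)
#' ## mineral oil with a long TE but no diffusion gradient: ~1.3e-3
#' residualSignalFraction(500, 75, 0, 0.04e-3)
#' @seealso [quantizationFloorPercent()], [simulateCombetPair()]
#' @export
residualSignalFraction <- function(te, t2, bValue, d) {
  if (any(te < 0)) stop("te must be >= 0", call. = FALSE)
  if (any(t2 <= 0)) stop("t2 must be > 0", call. = FALSE)
  if (any(bValue < 0)) stop("bValue must be >= 0", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  exp(-te / t2 - bValue * d)
}

#' Quantization floor of signed integer image storage
#'
#' The smallest representable positive signal as a percentage of full
#' scale: `100 / 2^(bitDepth - 1)`. For the usual signed 16-bit storage
#' this is 100/32768, about 3.1e-3 percent.
#'
#' @param bitDepth integer number of bits including the sign bit, >= 2;
#'   default 16.
#' @return the floor in percent of full scale.
#'
#' @examples
#' quantizationFloorPercent()    # 3.05e-3 %
#' quantizationFloorPercent(8)   # 0.78 %
#' @export
quantizationFloorPercent <- function(bitDepth = 16L) {
  if (length(bitDepth) != 1L || !is.finite(bitDepth) ||
      bitDepth != round(bitDepth) || bitDepth < 2)
    stop("bitDepth must be a single integer >= 2", call. = FALSE)
  100 / 2^(bitDepth - 1)
}

## noiseless per-channel amplitude matrix (before coil sensitivities)
.noiselessAmplitude <- function(phantom, params, amplitude,
                                te = params@te, bValue = params@bValue) {
  map <- phantom@regionMap
  rel <- matrix(0, nrow(map), ncol(map))
  for (lab in sort(unique(as.integer(map)))) {
    if (lab == 0L) next
    rel[map == lab] <- relativeSignal(regionTissue(phantom, lab),
                                      params@tr, te, bValue)
  }
  amplitude * phantom@sliceThickness * rel
}

#' Simulate one multichannel magnitude acquisition
#'
#' For every pixel, each coil channel receives the complex signal
#' `sensitivity_k * A` where `A = amplitude * sliceThickness *`
#' [relativeSignal()] of the pixel's region; independent Gaussian noise of
#' SD `noiseSigma` is added to the real and imaginary parts of every
#' channel, and the output pixel is the root sum of squares over channels.
#' Optional signed 16-bit quantization (relative to the maximum noiseless
#' TE = 0, b = 0 signal) is applied last. The noise stream is seeded from
#' `params@seed`, so identical inputs reproduce bit-identical images.
#'
#' @param phantom a [PhantomSpec-class].
#' @param params a [SequenceParams-class].
#' @param amplitude system gain: noiseless per-channel signal amplitude per
#'   mm of slice thickness at unit relative signal, default 1.
#' @param phantomId label recorded in the output image, default "phantom".
#' @return a [MagnitudeImage-class].
#'
#' @examples
#' ph <- cylindricalPhantom(32, TissueProperties(3505, 2390, 2.1e-3))
#' img <- simulateScan(ph, SequenceParams(3000, 37, nChannels = 4,
#'                                        noiseSigma = 1, seed = 2))
#' img
#' @seealso [simulateCombetPair()], [simulateSeries()], [amplitudeForSNR()]
#' @export
simulateScan <- function(phantom, params, amplitude = 1,
                         phantomId = "phantom") {
  stopifnot(is(phantom, "PhantomSpec"), is(params, "SequenceParams"))
  validObject(phantom); validObject(params)
  if (length(amplitude) != 1L || !is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be a single number >= 0", call. = FALSE)
  a <- .noiselessAmplitude(phantom, params, amplitude)
  npix <- length(a)
  sens <- params@coilSensitivities
  sigma <- params@noiseSigma
  sumsq <- .withSeed(params@seed, function() {
    acc <- matrix(0, nrow(a), ncol(a))
    for (k in seq_len(params@nChannels)) {
      re <- a * Re(sens[k])
      im <- a * Im(sens[k])
      if (sigma > 0) {
        re <- re + stats::rnorm(npix, 0, sigma)
        im <- im + stats::rnorm(npix, 0, sigma)
      }
      acc <- acc + re^2 + im^2
    }
    acc
  })
  px <- sqrt(sumsq)
  if (params@quantize16bit) {
    a0 <- .noiselessAmplitude(phantom, params, amplitude, te = 0, bValue = 0)
    full <- max(sqrt(a0^2 * sum(Mod(sens)^2)))
    if (full <= 0) stop("cannot quantize: phantom has no signal", call. = FALSE)
    px <- round(px / full * 32767)
  }
  new("MagnitudeImage", pixels = px, params = params,
      phantomId = as.character(phantomId), pixelSize = phantom@pixelSize,
      sliceThickness = phantom@sliceThickness)
}

#' Simulate a signal/noise image pair
#'
#' The signal image is acquired at `params`; the noise image repeats the
#' acquisition with the echo time raised to `teMax` and the diffusion
#' weighting raised to `bMax`, all other parameters identical, so that the
#' object signal decays to the noise floor. The two images carry distinct
#' noise realizations (the noise-image seed is advanced deterministically).
#' A long-TE-only pair (noise image without diffusion weighting) is
#' obtained with `bMax` equal to the signal image's b-value.
#'
#' @inheritParams simulateScan
#' @param teMax noise-image echo time in ms, `>= params@te`.
#' @param bMax noise-image b-value in s/mm^2, `>= params@bValue`.
#' @return list with elements `signal` and `noise`, both
#'   [MagnitudeImage-class].
#'
#' @examples
#' ph <- cylindricalPhantom(32, TissueProperties(3505, 2390, 2.1e-3))
#' pr <- simulateCombetPair(ph, SequenceParams(3000, 37, nChannels = 4,
#'                          noiseSigma = 1, seed = 5),
#'                          teMax = 500, bMax = 18000)
#' pr$noise
#' @export
simulateCombetPair <- function(phantom, params, teMax, bMax, amplitude = 1,
                               phantomId = "phantom") {
  stopifnot(is(params, "SequenceParams"))
  if (teMax < params@te)
    stop("teMax must be >= the signal-image TE", call. = FALSE)
  if (bMax < params@bValue)
    stop("bMax must be >= the signal-image b-value", call. = FALSE)
  noiseParams <- params
  noiseParams@te <- as.numeric(teMax)
  noiseParams@bValue <- as.numeric(bMax)
  noiseParams@seed <- as.integer((params@seed + 1L) %% .Machine$integer.max)
  list(signal = simulateScan(phantom, params, amplitude, phantomId),
       noise = simulateScan(phantom, noiseParams, amplitude, phantomId))
}

#' Simulate repeated acquisitions
#'
#' Repeats [simulateScan()] with per-repeat seeds derived from the master
#' seed by fixed unit increments, so the series is reproducible
#' element-wise and all repeats carry independent noise.
#'
#' @inheritParams simulateScan
#' @param nRepeats number of repeated scans, >= 1.
#' @return list of [MagnitudeImage-class], length `nRepeats`.
#'
#' @examples
#' ph <- cylindricalPhantom(32, TissueProperties(196, 75, 0.04e-3))
#' reps <- simulateSeries(ph, SequenceParams(3000, 37, noiseSigma = 1,
#'                        seed = 11), nRepeats = 2)
#' @export
simulateSeries <- function(phantom, params, nRepeats, amplitude = 1,
                           phantomId = "phantom") {
  if (length(nRepeats) != 1L || !is.finite(nRepeats) ||
      nRepeats != round(nRepeats) || nRepeats < 1)
    stop("nRepeats must be a single integer >= 1", call. = FALSE)
  lapply(seq_len(nRepeats) - 1L, function(i) {
    p <- params
    p@seed <- as.integer((params@seed + i) %% .Machine$integer.max)
    simulateScan(phantom, p, amplitude, phantomId)
  })
}

#' System gain for a target amplitude SNR
#'
#' Returns the `amplitude` argument of [simulateScan()] for which the
#' noiseless root-sum-of-squares pixel value inside the given region equals
#' `targetSNR * noiseSigma`, i.e. the amplitude-domain SNR of the simulated
#' signal image equals `targetSNR`.
#'
#' @inheritParams simulateScan
#' @param targetSNR desired noiseless sum-of-squares amplitude over sigma.
#' @param label phantom region the target refers to, default 1.
#' @return the amplitude (intensity units per mm per unit relative signal).
#' @export
amplitudeForSNR <- function(phantom, params, targetSNR, label = 1L) {
  stopifnot(is(phantom, "PhantomSpec"), is(params, "SequenceParams"))
  if (params@noiseSigma <= 0)
    stop("params must have noiseSigma > 0", call. = FALSE)
  rel <- relativeSignal(regionTissue(phantom, label), params@tr, params@te,
                        params@bValue)
  if (rel <= 0) stop("region has no signal under these parameters", call. = FALSE)
  sos1 <- phantom@sliceThickness * rel *
    sqrt(sum(Mod(params@coilSensitivities)^2))
  targetSNR * params@noiseSigma / sos1
}
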