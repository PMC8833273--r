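#' @import methods
NULL

#' Relaxation and diffusion properties of one phantom region
#'
#' Container for the tissue (or phantom-material) constants that drive the
#' spin-echo/diffusion signal model: longitudinal and transverse relaxation
#' times, apparent diffusion coefficient, and relative proton density.
#'
#' @slot t1 longitudinal relaxation time T1 in ms (> 0).
#' @slot t2 transverse relaxation time T2 in ms (> 0).
#' @slot d apparent diffusion coefficient in mm^2/s (>= 0).
#' @slot protonDensity relative proton density, dimensionless (>= 0).
#'
#' @seealso [TissueProperties()], [relativeSignal()]
#' @export
setClass("TissueProperties",
  representation(t1 = "numeric", t2 = "numeric", d = "numeric",
                 protonDensity = "numeric"))

setValidity("TissueProperties", function(object) {
  msg <- character()
  for (s in c("t1", "t2", "d", "protonDensity")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, paste0(s, " must be a single finite number"))
  }
  if (length(msg)) return(msg)
  if (object@t1 <= 0) msg <- c(msg, "t1 must be > 0")
  if (object@t2 <= 0) msg <- c(msg, "t2 must be > 0")
  if (object@d < 0) msg <- c(msg, "d must be >= 0")
  if (object@protonDensity < 0) msg <- c(msg, "protonDensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Digital phantom specification
#'
#' A labelled pixel grid plus per-region tissue properties. Region labels in
#' `regionMap` are non-negative integers; label 0 is the background and is
#' implicitly signal-free (proton density 0). Every non-zero label must have
#' an entry in `regions` (a named list of [TissueProperties-class] objects,
#' names being the labels as character).
#'
#' @slot regionMap integer matrix of region labels.
#' @slot regions named list of [TissueProperties-class], one per non-zero label.
#' @slot pixelSize in-plane pixel size in mm.
#' @slot sliceThickness slice thickness in mm; the simulated signal amplitude
#'   scales linearly with it.
#'
#' @seealso [cylindricalPhantom()], [simulateScan()]
#' @export
setClass("PhantomSpec",
  representation(regionMap = "matrix", regions = "list",
                 pixelSize = "numeric", sliceThickness = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  rm_ <- object@regionMap
  if (!is.numeric(rm_) && !is.integer(rm_)) msg <- c(msg, "regionMap must be an integer matrix")
  labs <- sort(unique(as.integer(rm_)))
  if (any(labs < 0L)) msg <- c(msg, "region labels must be >= 0 (0 = background)")
  need <- as.character(labs[labs > 0L])
  missing <- setdiff(need, names(object@regions))
  if (length(missing))
    msg <- c(msg, paste0("regionMap labels without tissue entry: ",
                         paste(missing, collapse = ", ")))
  if (!all(vapply(object@regions, is, logical(1), "TissueProperties")))
    msg <- c(msg, "all regions entries must be TissueProperties")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Pulse-sequence and acquisition parameters
#'
#' Repetition time, echo time, diffusion weighting, receive-chain geometry
#' and the noise model of one simulated (or recorded) acquisition.
#' `noiseSigma` is the Gaussian standard deviation per channel and per
#' real/imaginary component, in image-intensity units.
#'
#' @slot tr repetition time in ms (> 0).
#' @slot te echo time in ms (>= 0).
#' @slot bValue diffusion weighting in s/mm^2 (>= 0).
#' @slot nChannels number of receive coil channels N (>= 1).
#' @slot noiseSigma per-channel, per-component Gaussian noise SD (>= 0).
#' @slot coilSensitivities complex per-channel gains, length `nChannels`.
#' @slot seed integer seed for the noise stream.
#' @slot quantize16bit logical; round pixel values to a signed 16-bit scale.
#'
#' @seealso [SequenceParams()], [simulateScan()]
#' @export
setClass("SequenceParams",
  representation(tr = "numeric", te = "numeric", bValue = "numeric",
                 nChannels = "integer", noiseSigma = "numeric",
                 coilSensitivities = "complex", seed = "integer",
                 quantize16bit = "logical"))

setValidity("SequenceParams", function(object) {
  msg <- character()
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single number > 0")
  if (length(object@te) != 1L || !is.finite(object@te) || object@te < 0)
    msg <- c(msg, "te must be a single number >= 0")
  if (length(object@bValue) != 1L || !is.finite(object@bValue) || object@bValue < 0)
    msg <- c(msg, "bValue must be a single number >= 0")
  if (length(object@nChannels) != 1L || is.na(object@nChannels) || object@nChannels < 1L)
    msg <- c(msg, "nChannels must be a single integer >= 1")
  if (length(object@noiseSigma) != 1L || !is.finite(object@noiseSigma) || object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be a single number >= 0")
  if (length(object@coilSensitivities) != object@nChannels)
    msg <- c(msg, "coilSensitivities must have length nChannels")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@quantize16bit) != 1L || is.na(object@quantize16bit))
    msg <- c(msg, "quantize16bit must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Magnitude MR image with acquisition metadata
#'
#' A 2-D non-negative pixel array after root-sum-of-squares magnitude
#' reconstruction, together with the [SequenceParams-class] it was acquired
#' (or simulated) with and the pixel geometry needed for the NIfTI header.
#'
#' @slot pixels numeric matrix of non-negative intensities.
#' @slot params the acquisition [SequenceParams-class].
#' @slot phantomId character label of the imaged object.
#' @slot pixelSize in-plane pixel size in mm.
#' @slot sliceThickness slice thickness in mm.
#'
#' @seealso [simulateScan()], [readMagnitudeImage()], [writeMagnitudeImage()]
#' @export
setClass("MagnitudeImage",
  representation(pixels = "matrix", params = "SequenceParams",
                 phantomId = "character", pixelSize = "numeric",
                 sliceThickness = "numeric"))

setValidity("MagnitudeImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  else if (any(!is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  else if (any(object@pixels < 0)) msg <- c(msg, "pixels must be non-negative")
  if (length(object@phantomId) != 1L) msg <- c(msg, "phantomId must be a single string")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Region-of-interest specification
#'
#' Either a circular ROI defined by a center and an exact target pixel count
#' (the discretization picks the `targetPixelCount` grid pixels nearest the
#' center), or an explicit pixel mask given as a two-column (row, col)
#' integer matrix.
#'
#' @slot kind `"circular"` or `"mask"`.
#' @slot center numeric length-2 (row, col) center, circular kind only.
#' @slot targetPixelCount integer number of pixels, circular kind only.
#' @slot pixels two-column integer matrix of (row, col) pixels, mask kind only.
#'
#' @seealso [circularROI()], [maskROI()], [resolveROI()]
#' @export
setClass("ROISpec",
  representation(kind = "character", center = "numeric",
                 targetPixelCount = "integer", pixels = "matrix"))

setValidity("ROISpec", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% c("circular", "mask"))
    msg <- c(msg, "kind must be 'circular' or 'mask'")
  else if (object@kind == "circular") {
    if (length(object@center) != 2L || any(!is.finite(object@center)))
      msg <- c(msg, "center must be a finite (row, col) pair")
    if (length(object@targetPixelCount) != 1L || is.na(object@targetPixelCount) ||
        object@targetPixelCount < 1L)
      msg <- c(msg, "targetPixelCount must be a single integer >= 1")
  } else {
    if (!is.matrix(object@pixels) || ncol(object@pixels) != 2L ||
        nrow(object@pixels) < 1L)
      msg <- c(msg, "pixels must be a non-empty two-column (row, col) matrix")
    else if (any(object@pixels != round(object@pixels)) || any(object@pixels < 1))
      msg <- c(msg, "pixels must be positive integer coordinates")
  }
  if (length(msg)) msg else TRUE
})

#' Bias-corrected noise estimate
#'
#' The standard deviation measured in a signal-free region of a
#' sum-of-squares magnitude image (`rawSD`) and the corresponding estimate
#' of the per-channel Gaussian noise sigma (`correctedSD`), obtained by
#' dividing by the central-chi SD factor `sqrt(2N - beta(N)^2)`.
#'
#' @slot rawSD measured SD in the noise-image ROI (intensity units).
#' @slot correctedSD estimate of per-channel sigma (intensity units).
#' @slot nChannels number of coil channels used for the correction.
#'
#' @seealso [correctSD()], [sdCorrectionDivisor()]
#' @export
setClass("NoiseEstimate",
  representation(rawSD = "numeric", correctedSD = "numeric",
                 nChannels = "integer"))

setValidity("NoiseEstimate", function(object) {
  msg <- character()
  if (any(object@rawSD < 0)) msg <- c(msg, "rawSD must be >= 0")
  if (any(object@correctedSD < 0)) msg <- c(msg, "correctedSD must be >= 0")
  if (length(object@nChannels) != 1L || object@nChannels < 1L)
    msg <- c(msg, "nChannels must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' One SNR measurement
#'
#' Result record of an SNR estimator: mean signal in the ROI, corrected
#' noise, their ratio, the method label, the channel count and the
#' correction divisor actually applied.
#'
#' @slot method `"combet"`, `"delset"` or `"subtraction"`.
#' @slot meanSignal mean signal intensity over the ROI.
#' @slot noise corrected noise estimate (intensity units).
#' @slot snr dimensionless signal-to-noise ratio, `meanSignal / noise`.
#' @slot nChannels coil channels assumed by the correction (NA for the
#'   subtraction method, whose correction does not depend on N).
#' @slot roi the [ROISpec-class] the statistics were computed over.
#' @slot correctionDivisor the divisor applied to the raw SD.
#'
#' @seealso [estimateNoiseImageSNR()], [estimateSubtractionSNR()]
#' @export
setClass("SNREstimate",
  representation(method = "character", meanSignal = "numeric",
                 noise = "numeric", snr = "numeric", nChannels = "integer",
                 roi = "ROISpec", correctionDivisor = "numeric"))

setValidity("SNREstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("combet", "delset", "subtraction"))
    msg <- c(msg, "method must be combet, delset or subtraction")
  if (object@noise < 0) msg <- c(msg, "noise must be >= 0")
  if (object@noise > 0 &&
      abs(object@snr - object@meanSignal / object@noise) >
        1e-8 * max(1, abs(object@snr)))
    msg <- c(msg, "snr must equal meanSignal / noise")
  if (length(msg)) msg else TRUE
})

#' Sliding-window signal, noise and SNR maps
#'
#' Pixel-wise maps computed in a square sliding window: local mean of the
#' signal image, corrected local SD of the noise image, and their ratio.
#' Border pixels whose window leaves the image are flagged invalid (NA in
#' the maps, FALSE in `validMask`); no padding is applied.
#'
#' @slot signalMap numeric matrix, local mean signal.
#' @slot noiseMap numeric matrix, local corrected noise.
#' @slot snrMap numeric matrix, `signalMap / noiseMap`.
#' @slot window odd window side length in pixels.
#' @slot validMask logical matrix, TRUE where the window fits entirely.
#'
#' @seealso [slidingWindowMaps()]
#' @export
setClass("MapSet",
  representation(signalMap = "matrix", noiseMap = "matrix",
                 snrMap = "matrix", window = "integer",
                 validMask = "matrix"))

setValidity("MapSet", function(object) {
  msg <- character()
  dm <- dim(object@signalMap)
  if (!identical(dim(object@noiseMap), dm) || !identical(dim(object@snrMap), dm) ||
      !identical(dim(object@validMask), dm))
    msg <- c(msg, "all maps and validMask must share dimensions")
  if (length(object@window) != 1L || object@window < 3L || object@window %% 2L == 0L)
    msg <- c(msg, "window must be a single odd integer >= 3")
  if (length(msg)) msg else TRUE
})

#' Least-squares linearity result
#'
#' Slope, intercept and coefficient of determination of an ordinary
#' least-squares straight-line fit, used for the SNR versus effective
#' slice-thickness analysis.
#'
#' @slot slope fitted slope.
#' @slot intercept fitted intercept.
#' @slot rSquared coefficient of determination in `[0, 1]`.
#' @slot n number of points fitted.
#'
#' @seealso [linearityFit()]
#' @export
setClass("LinearityResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", n = "integer"))

setValidity("LinearityResult", function(object) {
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    "rSquared must lie in [0, 1]" else TRUE
})
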