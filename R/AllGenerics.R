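#' Accessor generics
#'
#' Small accessor generics for the package's S4 result and data classes.
#' Use these rather than reaching into slots with `@`.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("acqParams", function(x) standardGeneric("acqParams"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("rawSD", function(x) standardGeneric("rawSD"))

#' @rdname accessors
#' @export
setGeneric("correctedSD", function(x) standardGeneric("correctedSD"))

#' @rdname accessors
#' @export
setGeneric("snr", function(x) standardGeneric("snr"))

#' @rdname accessors
#' @export
setGeneric("meanSignal", function(x) standardGeneric("meanSignal"))

#' @rdname accessors
#' @export
setGeneric("noiseSD", function(x) standardGeneric("noiseSD"))

#' @rdname accessors
#' @export
setGeneric("snrMethod", function(x) standardGeneric("snrMethod"))

#' @rdname accessors
#' @export
setGeneric("signalMap", function(x) standardGeneric("signalMap"))

#' @rdname accessors
#' @export
setGeneric("noiseMap", function(x) standardGeneric("noiseMap"))

#' @rdname accessors
#' @export
setGeneric("snrMap", function(x) standardGeneric("snrMap"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname accessors
#' @export
setMethod("pixels", "MagnitudeImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("acqParams", "MagnitudeImage", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("nChannels", "SequenceParams", function(x) x@nChannels)

#' @rdname accessors
#' @export
setMethod("nChannels", "MagnitudeImage", function(x) x@params@nChannels)

#' @rdname accessors
#' @export
setMethod("nChannels", "NoiseEstimate", function(x) x@nChannels)

#' @rdname accessors
#' @export
setMethod("nChannels", "SNREstimate", function(x) x@nChannels)

#' @rdname accessors
#' @export
setMethod("rawSD", "NoiseEstimate", function(x) x@rawSD)

#' @rdname accessors
#' @export
setMethod("correctedSD", "NoiseEstimate", function(x) x@correctedSD)

#' @rdname accessors
#' @export
setMethod("snr", "SNREstimate", function(x) x@snr)

#' @rdname accessors
#' @export
setMethod("meanSignal", "SNREstimate", function(x) x@meanSignal)

#' @rdname accessors
#' @export
setMethod("noiseSD", "SNREstimate", function(x) x@noise)

#' @rdname accessors
#' @export
setMethod("snrMethod", "SNREstimate", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("signalMap", "MapSet", function(x) x@signalMap)

#' @rdname accessors
#' @export
setMethod("noiseMap", "MapSet", function(x) x@noiseMap)

#' @rdname accessors
#' @export
setMethod("snrMap", "MapSet", function(x) x@snrMap)

#' @rdname accessors
#' @export
setMethod("validMask", "MapSet", function(x) x@validMask)

#' @rdname accessors
#' @export
setMethod("windowSize", "MapSet", function(x) x@window)

setMethod("show", "TissueProperties", function(object) {
  cat(sprintf("TissueProperties: T1 = %g ms, T2 = %g ms, D = %g mm^2/s, PD = %g\n",
              object@t1, object@t2, object@d, object@protonDensity))
})

setMethod("show", "PhantomSpec", function(object) {
  dm <- dim(object@regionMap)
  cat(sprintf("PhantomSpec: %d x %d grid, %d region(s), pixel %g mm, slice %g mm\n",
              dm[1], dm[2], length(object@regions), object@pixelSize,
              object@sliceThickness))
})

setMethod("show", "SequenceParams", function(object) {
  cat(sprintf(
    "SequenceParams: TR = %g ms, TE = %g ms, b = %g s/mm^2, N = %d, sigma = %g, seed = %d%s\n",
    object@tr, object@te, object@bValue, object@nChannels, object@noiseSigma,
    object@seed, if (object@quantize16bit) ", 16-bit quantized" else ""))
})

setMethod("show", "MagnitudeImage", function(object) {
  dm <- dim(object@pixels)
  cat(sprintf("MagnitudeImage '%s': %d x %d pixels, range [%g, %g]\n",
              object@phantomId, dm[1], dm[2], min(object@pixels),
              max(object@pixels)))
  show(object@params)
})

setMethod("show", "ROISpec", function(object) {
  if (object@kind == "circular")
    cat(sprintf("ROISpec: circular, center (%g, %g), %d pixels\n",
                object@center[1], object@center[2], object@targetPixelCount))
  else
    cat(sprintf("ROISpec: mask, %d pixels\n", nrow(object@pixels)))
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: raw SD = %g, corrected SD = %g (N = %d, divisor = %g)\n",
              object@rawSD, object@correctedSD, object@nChannels,
              sdCorrectionDivisor(object@nChannels)))
})

setMethod("show", "SNREstimate", function(object) {
  cat(sprintf("SNREstimate [%s]: mean signal = %g, noise = %g, SNR = %g\n",
              object@method, object@meanSignal, object@noise, object@snr))
})

setMethod("show", "MapSet", function(object) {
  dm <- dim(object@signalMap)
  cat(sprintf("MapSet: %d x %d, window %d x %d, %d valid pixel(s)\n",
              dm[1], dm[2], object@window, object@window,
              sum(object@validMask)))
})

setMethod("show", "LinearityResult", function(object) {
  cat(sprintf("LinearityResult: slope = %g, intercept = %g, R^2 = %.4f (n = %d)\n",
              object@slope, object@intercept, object@rSquared, object@n))
})
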