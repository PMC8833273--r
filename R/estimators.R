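## The SNR estimators. All standard deviations are sample SDs (n - 1
## denominator), which matters for the small 52-pixel ROIs used in
## practice. A noise SD of exactly zero signals a broken acquisition
## (e.g. an all-zero noise image) and raises an error rather than
## returning an infinite SNR.

.checkSameShape <- function(a, b) {
  if (!identical(dim(pixels(a)), dim(pixels(b))))
    stop("images must share the same shape", call. = FALSE)
}

#' SNR from a signal image and a signal-free noise image
#'
#' Mean signal intensity over the ROI of the signal image divided by the
#' bias-corrected SD over the same ROI of the noise image
#' (see [correctSD()]). This is the shared computation of the two
#' noise-image methods: the maximum-b-plus-longest-TE method ("combet")
#' and the long-TE-only double-echo method ("delset") differ only in how
#' the noise image was acquired, which the `method` label records.
#'
#' @param signalImg [MagnitudeImage-class] signal image.
#' @param noiseImg [MagnitudeImage-class] noise image, same shape.
#' @param roi an [ROISpec-class]; the same resolved pixel set is applied to
#'   both images.
#' @param nChannels coil channels for the correction; defaults to the noise
#'   image's metadata.
#' @param method `"combet"` (default) or `"delset"`.
#' @return an [SNREstimate-class].
#'
#' @examples
#' ph <- cylindricalPhantom(64, TissueProperties(3505, 2390, 2.1e-3))
#' sp <- SequenceParams(3000, 37, nChannels = 4, noiseSigma = 1, seed = 3)
#' pr <- simulateCombetPair(ph, sp, teMax = 500, bMax = 18000,
#'                          amplitude = amplitudeForSNR(ph, sp, 50))
#' estimateNoiseImageSNR(pr$signal, pr$noise, circularROI(c(32.5, 32.5), 52))
#' @seealso [estimateSubtractionSNR()], [slidingWindowMaps()]
#' @export
estimateNoiseImageSNR <- function(signalImg, noiseImg, roi,
                                  nChannels = NULL,
                                  method = c("combet", "delset")) {
  stopifnot(is(signalImg, "MagnitudeImage"), is(noiseImg, "MagnitudeImage"))
  method <- match.arg(method)
  .checkSameShape(signalImg, noiseImg)
  if (is.null(nChannels)) nChannels <- nChannels(noiseImg)
  n <- .checkChannels(nChannels)
  px <- resolveROI(roi, dim(pixels(signalImg)))
  if (nrow(px) < 2L)
    stop("ROI must contain at least 2 pixels to estimate an SD", call. = FALSE)
  m <- mean(.roiValues(signalImg, px))
  s <- stats::sd(.roiValues(noiseImg, px))
  if (s == 0)
    stop("degenerate noise image: SD over the ROI is zero", call. = FALSE)
  ne <- correctSD(s, n)
  new("SNREstimate", method = method, meanSignal = m,
      noise = correctedSD(ne), snr = m / correctedSD(ne), nChannels = n,
      roi = roi, correctionDivisor = sdCorrectionDivisor(n))
}

#' SNR from two repeated acquisitions (subtraction method)
#'
#' Noise is estimated from the pixel-wise difference of two images acquired
#' under identical conditions: the sample SD of the difference over the
#' ROI, divided by `sqrt(2)` ([subtractionNoise()]) to undo the variance
#' doubling of the subtraction. The mean signal is pooled over the ROI of
#' both images. This reference method needs no channel-count correction.
#'
#' @param img1,img2 [MagnitudeImage-class] repeats, identical shape and
#'   acquisition parameters.
#' @param roi an [ROISpec-class].
#' @return an [SNREstimate-class] with method `"subtraction"`.
#'
#' @examples
#' ph <- cylindricalPhantom(64, TissueProperties(196, 75, 0.04e-3))
#' sp <- SequenceParams(3000, 37, noiseSigma = 1, seed = 9)
#' reps <- simulateSeries(ph, sp, 2, amplitude = amplitudeForSNR(ph, sp, 40))
#' estimateSubtractionSNR(reps[[1]], reps[[2]], circularROI(c(32.5, 32.5), 52))
#' @export
estimateSubtractionSNR <- function(img1, img2, roi) {
  stopifnot(is(img1, "MagnitudeImage"), is(img2, "MagnitudeImage"))
  .checkSameShape(img1, img2)
  px <- resolveROI(roi, dim(pixels(img1)))
  if (nrow(px) < 2L)
    stop("ROI must contain at least 2 pixels to estimate an SD", call. = FALSE)
  v1 <- .roiValues(img1, px)
  v2 <- .roiValues(img2, px)
  s <- stats::sd(v1 - v2)
  if (s == 0)
    stop("degenerate difference image: the two images are identical over the ROI",
         call. = FALSE)
  noise <- subtractionNoise(s)
  m <- mean(c(v1, v2))
  new("SNREstimate", method = "subtraction", meanSignal = m, noise = noise,
      snr = m / noise, nChannels = NA_integer_, roi = roi,
      correctionDivisor = sqrt(2))
}

#' Sliding-window signal, noise and SNR maps
#'
#' Computes, for every pixel whose square window fits entirely inside the
#' image, the local mean of the signal image and the corrected local SD of
#' the noise image, and divides them pixel-by-pixel into an SNR map.
#' Border pixels are flagged invalid (NA); no padding is applied, so no
#' map value mixes fabricated statistics.
#'
#' @inheritParams estimateNoiseImageSNR
#' @param window odd window side length in pixels, >= 3 and no larger than
#'   either image dimension; default 7.
#' @return a [MapSet-class].
#'
#' @examples
#' ph <- cylindricalPhantom(32, TissueProperties(3505, 2390, 2.1e-3))
#' sp <- SequenceParams(3000, 37, nChannels = 4, noiseSigma = 1, seed = 4)
#' pr <- simulateCombetPair(ph, sp, 500, 18000, amplitude = 10)
#' maps <- slidingWindowMaps(pr$signal, pr$noise)
#' maps
#' @export
slidingWindowMaps <- function(signalImg, noiseImg, window = 7L,
                              nChannels = NULL) {
  stopifnot(is(signalImg, "MagnitudeImage"), is(noiseImg, "MagnitudeImage"))
  .checkSameShape(signalImg, noiseImg)
  if (length(window) != 1L || !is.finite(window) || window != round(window))
    stop("window must be a single integer", call. = FALSE)
  window <- as.integer(window)
  dm <- dim(pixels(signalImg))
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window < 3L || window > min(dm))
    stop("window must be >= 3 and fit inside the image", call. = FALSE)
  if (is.null(nChannels)) nChannels <- nChannels(noiseImg)
  n <- .checkChannels(nChannels)
  div <- sdCorrectionDivisor(n)
  half <- window %/% 2L
  sig <- pixels(signalImg)
  noi <- pixels(noiseImg)
  sMap <- matrix(NA_real_, dm[1], dm[2])
  nMap <- matrix(NA_real_, dm[1], dm[2])
  valid <- matrix(FALSE, dm[1], dm[2])
  for (r in (half + 1L):(dm[1] - half)) {
    rs <- (r - half):(r + half)
    for (cl in (half + 1L):(dm[2] - half)) {
      cs <- (cl - half):(cl + half)
      sMap[r, cl] <- mean(sig[rs, cs])
      nMap[r, cl] <- stats::sd(noi[rs, cs]) / div
      valid[r, cl] <- TRUE
    }
  }
  snrM <- sMap / nMap
  snrM[valid & nMap == 0] <- NA_real_
  new("MapSet", signalMap = sMap, noiseMap = nMap, snrMap = snrM,
      window = window, validMask = valid)
}

#' Coefficient of variation of repeated SNR measurements
#'
#' Sample SD divided by the mean; the repeatability measure for SNR
#' estimates over a series of identical scans.
#'
#' @param snrValues numeric vector of at least two values with non-zero
#'   mean.
#' @return the dimensionless coefficient of variation.
#'
#' @examples
#' coefficientOfVariation(c(1, 2, 3))  # 0.5
#' @export
coefficientOfVariation <- function(snrValues) {
  if (!is.numeric(snrValues) || length(snrValues) < 2L ||
      any(!is.finite(snrValues)))
    stop("snrValues must contain at least 2 finite values", call. = FALSE)
  m <- mean(snrValues)
  if (m == 0) stop("mean of snrValues is zero", call. = FALSE)
  stats::sd(snrValues) / m
}

#' Straight-line fit of SNR against effective slice thickness
#'
#' Ordinary least-squares fit `y = slope * x + intercept` with the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`. When `y` is
#' constant (`SS_tot = 0`) the fit explains nothing and `R^2` is 0.
#'
#' @param x predictor values (e.g. effective slice thickness in mm), at
#'   least 3, not all equal.
#' @param y response values (e.g. measured SNR), same length.
#' @return a [LinearityResult-class].
#'
#' @examples
#' linearityFit(1:6, 2 * (1:6))  # slope 2, R^2 = 1
#' @export
linearityFit <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("x and y must be numeric vectors of equal length", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 points are required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::var(x) == 0) stop("x values must not all be equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) 0 else 1 - ssRes / ssTot
  cf <- stats::coef(fit)
  new("LinearityResult", slope = unname(cf[2]), intercept = unname(cf[1]),
      rSquared = max(0, min(1, r2)), n = length(x))
}
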