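## Central-chi moment machinery behind the multichannel magnitude-noise
## corrections. A root-sum-of-squares magnitude pixel built from N coil
## channels with independent Gaussian noise (SD sigma per real/imaginary
## component) follows, in signal-free regions, a central chi distribution
## with 2N degrees of freedom scaled by sigma. Its mean is sigma * beta(N)
## and its SD is sigma * sqrt(2N - beta(N)^2); dividing a measured noise SD
## by that factor recovers the per-channel sigma.

.checkChannels <- function(nChannels) {
  if (length(nChannels) < 1L || !is.numeric(nChannels) ||
      any(!is.finite(nChannels)) || any(nChannels != round(nChannels)) ||
      any(nChannels < 1))
    stop("nChannels must be integer-valued and >= 1", call. = FALSE)
  as.integer(nChannels)
}

#' Mean of the central chi distribution for N coil channels
#'
#' Computes `beta(N) = sqrt(pi/2) * (2N-1)!! / (2^(N-1) * (N-1)!)`, the mean
#' of a central chi variate with `2N` degrees of freedom at unit per-channel
#' sigma. This is the expected background level of a sum-of-squares
#' magnitude image containing pure noise. The double factorial is evaluated
#' in log space through `(2N-1)!! = (2N)! / (2^N N!)`, so the result stays
#' accurate far beyond the point where naive factorials overflow.
#'
#' @param nChannels number of coil channels N, integer-valued, >= 1. May be
#'   a vector.
#' @return `beta(N)`, dimensionless; numerically equal to
#'   `sqrt(2) * gamma(N + 1/2) / gamma(N)`.
#'
#' @examples
#' chiBeta(1)            # sqrt(pi/2) = 1.2533, the Rayleigh mean
#' chiBeta(c(2, 16, 64)) # stable for large N
#' @seealso [sdCorrectionDivisor()], [correctSD()]
#' @export
chiBeta <- function(nChannels) {
  n <- .checkChannels(nChannels)
  ## log((2n-1)!!) = lgamma(2n) - (n-1)*log(2) - lgamma(n)
  logdf <- lgamma(2 * n) - (n - 1) * log(2) - lgamma(n)
  sqrt(pi / 2) * exp(logdf - (n - 1) * log(2) - lgamma(n))
}

#' SD correction divisor for sum-of-squares magnitude noise
#'
#' Returns `sqrt(2N - beta(N)^2)`, the standard deviation of a central chi
#' variate with `2N` degrees of freedom at unit per-channel sigma. The SD
#' measured in a signal-free region of a sum-of-squares magnitude image is
#' this factor times the per-channel Gaussian sigma.
#'
#' The divisor increases monotonically with N and approaches `sqrt(1/2)`
#' as N grows (the chi distribution tends to a Gaussian of variance 1/2).
#'
#' @inheritParams chiBeta
#' @return the dimensionless divisor; e.g. 0.6551 for N = 1 (Rayleigh SD).
#'
#' @examples
#' sdCorrectionDivisor(1)   # sqrt(2 - pi/2)
#' sdCorrectionDivisor(16)
#' @seealso [chiBeta()], [correctSD()]
#' @export
sdCorrectionDivisor <- function(nChannels) {
  n <- .checkChannels(nChannels)
  sqrt(2 * n - chiBeta(n)^2)
}

#' Correct a measured noise SD for magnitude-reconstruction bias
#'
#' Converts the SD measured in a signal-free ROI of a sum-of-squares
#' magnitude image into an estimate of the per-channel Gaussian noise sigma
#' by dividing by [sdCorrectionDivisor()]. The premise is that the ROI
#' contains pure noise: residual signal inflates the raw SD and is not
#' corrected for here.
#'
#' @param rawSD measured standard deviation (intensity units), >= 0.
#' @param nChannels number of coil channels N, integer-valued, >= 1.
#' @return a [NoiseEstimate-class] holding `rawSD`, the corrected SD and N.
#'
#' @examples
#' correctSD(0.65514, 1)      # recovers sigma = 1 for a Rayleigh background
#' correctedSD(correctSD(2.8, 16))
#' @seealso [sdCorrectionDivisor()], [estimateNoiseImageSNR()]
#' @export
correctSD <- function(rawSD, nChannels) {
  if (!is.numeric(rawSD) || any(!is.finite(rawSD)) || any(rawSD < 0))
    stop("rawSD must be finite and >= 0", call. = FALSE)
  n <- .checkChannels(nChannels)
  if (length(n) != 1L)
    stop("nChannels must be a single integer", call. = FALSE)
  new("NoiseEstimate", rawSD = as.numeric(rawSD),
      correctedSD = as.numeric(rawSD) / sdCorrectionDivisor(n),
      nChannels = n)
}

#' Noise of one image from the SD of a difference image
#'
#' The difference of two independent, identically distributed images has
#' twice the single-image noise variance, so the single-image noise is the
#' difference-image SD divided by `sqrt(2)`.
#'
#' @param sdSub standard deviation measured in an ROI of the difference
#'   image (intensity units), >= 0.
#' @return the estimated single-image noise SD.
#'
#' @examples
#' subtractionNoise(sqrt(2))  # 1
#' @seealso [estimateSubtractionSNR()]
#' @export
subtractionNoise <- function(sdSub) {
  if (!is.numeric(sdSub) || any(!is.finite(sdSub)) || any(sdSub < 0))
    stop("sdSub must be finite and >= 0", call. = FALSE)
  sdSub / sqrt(2)
}

#' Expected sum-of-squares magnitude of a noisy multichannel pixel
#'
#' Mean of a noncentral chi variate with `2N` degrees of freedom:
#' the expected magnitude-image pixel value when the noiseless
#' root-sum-of-squares amplitude is `sos` and each channel component
#' carries Gaussian noise of SD `sigma`. At high amplitude-to-noise ratio
#' this tends to `sos`; at low ratio the magnitude operation biases the
#' mean upward (the noise floor), which is why magnitude-image SNR
#' estimators over-read weak signals.
#'
#' Computed by numerical integration of the scaled noncentral chi-squared
#' density; no simulation is involved.
#'
#' @param sos noiseless root-sum-of-squares amplitude(s), >= 0.
#' @param sigma per-channel, per-component noise SD, > 0.
#' @param nChannels number of coil channels N, integer-valued, >= 1.
#' @return expected magnitude pixel value, same units as `sos`.
#'
#' @examples
#' expectedMagnitude(0, 1, 4)    # noise floor = chiBeta(4)
#' expectedMagnitude(50, 1, 16)  # barely above 50
#' @seealso [chiBeta()], [simulateScan()]
#' @export
expectedMagnitude <- function(sos, sigma, nChannels) {
  if (!is.numeric(sos) || any(!is.finite(sos)) || any(sos < 0))
    stop("sos must be finite and >= 0", call. = FALSE)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single number > 0", call. = FALSE)
  n <- .checkChannels(nChannels)
  if (length(n) != 1L) stop("nChannels must be a single integer", call. = FALSE)
  df <- 2 * n
  vapply(sos, function(a) {
    ncp <- (a / sigma)^2
    m <- df + ncp
    s <- sqrt(2 * (df + 2 * ncp))
    sigma * stats::integrate(function(q) sqrt(q) * stats::dchisq(q, df, ncp),
                             lower = max(0, m - 40 * s), upper = m + 40 * s,
                             rel.tol = 1e-10)$value
  }, numeric(1))
}
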