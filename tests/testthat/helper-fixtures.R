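## Shared fixtures and independent oracles for the test suite.

## Tissue constants of the two reference phantom materials.
waterTissue <- function() TissueProperties(t1 = 3505, t2 = 2390, d = 2.1e-3)
oilTissue <- function() TissueProperties(t1 = 196, t2 = 75, d = 0.04e-3)

## Wrap a bare pixel matrix in a MagnitudeImage for hand-crafted tests.
makeImg <- function(px, nChannels = 1L, te = 37, bValue = 0, tr = 3000,
                    noiseSigma = 1, seed = 1L) {
  new("MagnitudeImage", pixels = px,
      params = SequenceParams(tr = tr, te = te, bValue = bValue,
                              nChannels = nChannels, noiseSigma = noiseSigma,
                              seed = seed),
      phantomId = "test", pixelSize = 1, sliceThickness = 1)
}

## Raw moment E[X^k] of a central chi variate with 2*nChannels degrees of
## freedom (unit sigma), from the gamma-function closed form.
chiRawMoment <- function(nChannels, k) {
  2^(k / 2) * exp(lgamma(nChannels + k / 2) - lgamma(nChannels))
}

## Sampling standard error of the bias-corrected SD computed from nPix iid
## scaled chi pixels (delta method on the sample SD).
chiSdSE <- function(nPix, nChannels, sigma = 1) {
  v <- chiRawMoment(nChannels, 2) - chiRawMoment(nChannels, 1)^2
  mu4 <- chiRawMoment(nChannels, 4) -
    4 * chiRawMoment(nChannels, 3) * chiRawMoment(nChannels, 1) +
    6 * chiRawMoment(nChannels, 2) * chiRawMoment(nChannels, 1)^2 -
    3 * chiRawMoment(nChannels, 1)^4
  sigma * sqrt((mu4 - v^2) / (4 * nPix * v)) / sdCorrectionDivisor(nChannels)
}

## Monte-Carlo oracle for the mean and SD of a noisy sum-of-squares
## magnitude pixel: noiseless root-sum-of-squares amplitude `sos`,
## per-channel/component noise SD `sigma`. Independent of the simulator
## (draws scaled noncentral chi-squared variates directly).
magnitudeMomentsMC <- function(sos, sigma, nChannels, nDraws = 2e5,
                               seed = 4242) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- sigma * sqrt(rchisq(nDraws, df = 2 * nChannels,
                           ncp = (sos / sigma)^2))
  list(mean = mean(m), sd = sd(m), n = nDraws)
}

## Disc membership mask of a cylindrical phantom's region map.
phantomMask <- function(phantom) regionMap(phantom) == 1L
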