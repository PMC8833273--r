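test_that("noise-image SNR composes the mean with the corrected SD", {
  ## signal 100 everywhere; noise ROI crafted so its sample SD equals the
  ## N = 1 correction divisor, hence corrected noise is 1 and SNR is 100
  sig <- makeImg(matrix(100, 4, 4))
  noiVals <- c(5, 5 + sqrt(2) * sqrt(2 - pi / 2))
  noi <- makeImg(matrix(noiVals, 4, 4))
  roi <- maskROI(cbind(c(1, 2), c(1, 1)))
  est <- estimateNoiseImageSNR(sig, noi, roi, nChannels = 1L)
  expect_equal(noiseSD(est), 1, tolerance = 1e-12)
  expect_equal(snr(est), 100, tolerance = 1e-12)
  expect_identical(snrMethod(est), "combet")
  expect_equal(est@correctionDivisor, sdCorrectionDivisor(1))

  ## an all-zero signal image has SNR 0 for any valid noise image
  zero <- makeImg(matrix(0, 4, 4))
  expect_equal(snr(estimateNoiseImageSNR(zero, noi, roi, nChannels = 1L)), 0)
})

test_that("degenerate noise images raise an error instead of infinite SNR", {
  sig <- makeImg(matrix(100, 4, 4))
  flat <- makeImg(matrix(3, 4, 4))
  roi <- maskROI(cbind(c(1, 2, 3), c(1, 1, 1)))
  expect_error(estimateNoiseImageSNR(sig, flat, roi, nChannels = 1L),
               "degenerate")
  expect_error(estimateNoiseImageSNR(sig, makeImg(matrix(1, 3, 3)), roi),
               "shape")
})

test_that("subtraction estimator reproduces the hand-worked example", {
  img1 <- makeImg(matrix(c(10, 12), 1, 2))
  img2 <- makeImg(matrix(c(12, 10), 1, 2))
  roi <- maskROI(cbind(c(1, 1), c(1, 2)))
  est <- estimateSubtractionSNR(img1, img2, roi)
  expect_equal(sd(c(-2, 2)), 2.8284, tolerance = 1e-4)  # sanity on the oracle
  expect_equal(noiseSD(est), 2)
  expect_equal(meanSignal(est), 11)
  expect_equal(snr(est), 5.5)
  expect_identical(snrMethod(est), "subtraction")
  expect_error(estimateSubtractionSNR(img1, img1, roi), "identical")
})

test_that("both estimators recover their analytic measurands on simulated phantoms", {
  ## The noise-image estimator measures E[magnitude] / sigma; the
  ## subtraction estimator measures E[magnitude] / SD(magnitude). At high
  ## amplitude both tend to the amplitude-domain SNR; at low amplitude the
  ## magnitude operation biases them upward (noncentral-chi noise floor).
  ph <- cylindricalPhantom(96, waterTissue(), diameter = 100, pixelSize = 1.2)
  roi <- circularROI(c(48.5, 48.5), 1264)
  nRep <- 4L
  for (nCh in c(1L, 4L, 16L)) {
    for (target in c(5, 20, 100)) {
      params <- SequenceParams(tr = 3000, te = 37, nChannels = nCh,
                               noiseSigma = 1,
                               seed = 1000L + 10L * nCh + as.integer(target))
      amp <- amplitudeForSNR(ph, params, target)
      mc <- magnitudeMomentsMC(target, 1, nCh, seed = 7L * nCh + target)

      com <- vapply(seq_len(nRep), function(i) {
        p <- params; p@seed <- params@seed + 100L * i
        pr <- simulateCombetPair(ph, p, teMax = 500, bMax = 18000,
                                 amplitude = amp)
        snr(estimateNoiseImageSNR(pr$signal, pr$noise, roi))
      }, numeric(1))
      expect_equal(mean(com), mc$mean, tolerance = 0.04,
                   label = sprintf("combet estimate (N=%d, target=%g)",
                                   nCh, target))

      sub <- vapply(seq_len(nRep), function(i) {
        p <- params; p@seed <- params@seed + 100L * i + 50L
        reps <- simulateSeries(ph, p, 2, amplitude = amp)
        snr(estimateSubtractionSNR(reps[[1]], reps[[2]], roi))
      }, numeric(1))
      expect_equal(mean(sub), mc$mean / mc$sd, tolerance = 0.04,
                   label = sprintf("subtraction estimate (N=%d, target=%g)",
                                   nCh, target))

      ## in the high-amplitude regime both agree with the amplitude SNR
      if (target == 100) {
        expect_equal(mean(com), target, tolerance = 0.03)
        expect_equal(mean(sub), target, tolerance = 0.03)
        expect_equal(mean(com), mean(sub), tolerance = 0.03)
      }
    }
  }
})

test_that("SNR estimates scale with amplitude and inversely with sigma", {
  ph <- cylindricalPhantom(64, oilTissue())
  roi <- circularROI(c(32.5, 32.5), 300)
  base <- SequenceParams(tr = 3000, te = 37, nChannels = 4L, noiseSigma = 1,
                         seed = 21L)
  pr1 <- simulateCombetPair(ph, base, 500, 18000, amplitude = 40)
  s1 <- snr(estimateNoiseImageSNR(pr1$signal, pr1$noise, roi))
  pr2 <- simulateCombetPair(ph, base, 500, 18000, amplitude = 80)
  s2 <- snr(estimateNoiseImageSNR(pr2$signal, pr2$noise, roi))
  expect_equal(s2 / s1, 2, tolerance = 0.1)
  twoSigma <- base; twoSigma@noiseSigma <- 2
  pr3 <- simulateCombetPair(ph, twoSigma, 500, 18000, amplitude = 40)
  s3 <- snr(estimateNoiseImageSNR(pr3$signal, pr3$noise, roi))
  expect_equal(s1 / s3, 2, tolerance = 0.1)
})

test_that("a long-TE-only noise image biases the SNR low for long-T2 phantoms", {
  ph <- cylindricalPhantom(64, waterTissue())
  params <- SequenceParams(tr = 3000, te = 37, nChannels = 4L,
                           noiseSigma = 1, seed = 33L)
  amp <- amplitudeForSNR(ph, params, 40)
  combetPair <- simulateCombetPair(ph, params, teMax = 500, bMax = 18000,
                                   amplitude = amp)
  delsetPair <- simulateCombetPair(ph, params, teMax = 500, bMax = 0,
                                   amplitude = amp)
  roi <- circularROI(c(32.5, 32.5), 300)
  com <- estimateNoiseImageSNR(combetPair$signal, combetPair$noise, roi)
  del <- estimateNoiseImageSNR(delsetPair$signal, delsetPair$noise, roi,
                               method = "delset")
  expect_lt(snr(del), snr(com))
  ## inside a uniform phantom the residual signal raises the noise-image SD
  ## from sigma*divisor toward sigma, i.e. by up to 1/divisor (about 1.44)
  expect_gt(noiseSD(del), 1.2 * noiseSD(com))
})

test_that("coefficient of variation matches its definition and input checks", {
  expect_equal(coefficientOfVariation(c(5, 5, 5)), 0)
  expect_equal(coefficientOfVariation(c(1, 2, 3)), 0.5)
  expect_error(coefficientOfVariation(3), "at least 2")
  expect_error(coefficientOfVariation(c(-1, 1)), "zero")
})

test_that("repeated-scan SNR variability matches the chi sampling prediction", {
  ph <- cylindricalPhantom(64, oilTissue())
  roi <- circularROI(c(32.5, 32.5), 52)
  params <- SequenceParams(tr = 3000, te = 37, nChannels = 16L,
                           noiseSigma = 1, seed = 77L)
  amp <- amplitudeForSNR(ph, params, 60)
  snrs <- vapply(0:19, function(i) {
    p <- params; p@seed <- params@seed + 10L * i
    pr <- simulateCombetPair(ph, p, teMax = 500, bMax = 18000,
                             amplitude = amp)
    snr(estimateNoiseImageSNR(pr$signal, pr$noise, roi))
  }, numeric(1))
  cv <- coefficientOfVariation(snrs)
  expect_gt(cv, 0)
  ## dominant variance source: the 52-pixel noise SD estimate
  predicted <- chiSdSE(52, 16L) / 1  # relative, since corrected SD ~ sigma = 1
  expect_gt(cv, predicted / 3)
  expect_lt(cv, 3 * predicted)
})

test_that("linearity fit recovers exact lines and rejects degenerate input", {
  fit <- linearityFit(1:6, 2 * (1:6))
  expect_equal(fit@slope, 2)
  expect_equal(fit@intercept, 0)
  expect_equal(fit@rSquared, 1)
  flat <- linearityFit(1:5, rep(3, 5))
  expect_equal(flat@rSquared, 0)
  expect_error(linearityFit(1:2, 1:2), "3 points")
  expect_error(linearityFit(rep(1, 4), 1:4), "equal")
})

test_that("simulated SNR rises linearly with slice thickness", {
  thicknesses <- 1:6
  params <- SequenceParams(tr = 3000, te = 37, nChannels = 16L,
                           noiseSigma = 1, seed = 55L)
  snrs <- vapply(thicknesses, function(th) {
    ph <- cylindricalPhantom(64, oilTissue(), sliceThickness = th)
    p <- params; p@seed <- params@seed + th
    pr <- simulateCombetPair(ph, p, teMax = 500, bMax = 18000, amplitude = 8)
    snr(estimateNoiseImageSNR(pr$signal, pr$noise,
                              circularROI(c(32.5, 32.5), 1264)))
  }, numeric(1))
  fit <- linearityFit(thicknesses, snrs)
  expect_gt(fit@rSquared, 0.99)
  expect_gt(fit@slope, 0)
})
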