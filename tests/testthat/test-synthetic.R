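test_that("white noise generator is seeded, zero-mean and flat", {
  w1 <- whiteNoise(1, seed = 7)
  w2 <- whiteNoise(1, seed = 7)
  expect_identical(samples(w1), samples(w2))
  expect_false(identical(samples(w1), samples(whiteNoise(1, seed = 8))))

  w <- whiteNoise(10, seed = 3)
  x <- samples(w)
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))

  expect_error(whiteNoise(0, seed = 1), "duration")
  expect_error(whiteNoise(1, fs = -1, seed = 1), "fs")
})

test_that("60 s white noise has flat Fourier spectrum and unit entropy", {
  w <- whiteNoise(60, seed = 1)
  ps <- powerSpectrum(spectrogram(w, trim = 0.05))
  expect_lt(abs(fitSpectrumSlope(ps)$slope), 0.05)
  expect_gt(spectralEntropy(ps)$entropy, 1 - 0.02)
})

test_that("power-law generator realizes the requested spectral slope", {
  w <- powerLawSound(60, spectralSlope = -3, modExponent = 1, seed = 2)
  fit <- fitSpectrumSlope(powerSpectrum(spectrogram(w, trim = 0.05)))
  expect_gt(fit$slope, -3.6)
  expect_lt(fit$slope, -2.4)
})

test_that("realized slope is monotone in the requested slope", {
  slopes <- vapply(c(-6, -3, 0, 3), function(sl) {
    w <- powerLawSound(20, spectralSlope = sl, modExponent = 0, seed = 11)
    fitSpectrumSlope(powerSpectrum(spectrogram(w, trim = 0.05)))$slope
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  # the degenerate case is statistically indistinguishable from white noise
  expect_lt(abs(slopes[3]), 0.1)
})

test_that("envelope modulation power decays as fm^-alpha", {
  # wideband channels have low intrinsic envelope-fluctuation density, so
  # the imposed 1/f modulation trend dominates the measured marginal
  w <- powerLawSound(60, spectralSlope = 0, modExponent = 1, seed = 4)
  m <- welchMps(spectrogram(w, gaborSpec(480), trim = 0.05))
  mg <- mpsMarginals(m)
  fm <- as.numeric(names(mg$temporal))
  sel <- fm >= 1 & fm <= 16
  fit <- coef(lm(log(mg$temporal[sel]) ~ log(fm[sel])))[2]
  expect_gt(fit, -1.3)
  expect_lt(fit, -0.7)
})

test_that("harmonic generator produces resolved lines and AM peak", {
  # degenerate case: a single harmonic with no formants is a pure tone
  tone <- harmonicVocalization(0.5, f0 = 100, nHarmonics = 1, seed = 1)
  spec <- Mod(fft(samples(tone)))[1:11025]
  f <- (0:11024) * sampleRate(tone) / length(samples(tone))
  expect_lt(abs(f[which.max(spec)] - 100), 3)

  # resolved lines at k * 150 Hz in the narrowband spectrogram
  w <- harmonicVocalization(4, f0 = 150, nHarmonics = 40, seed = 1)
  ps <- powerSpectrum(spectrogram(w, trim = 0.05))
  fr <- attr(ps, "freqs")
  n <- length(ps)
  pk <- which(ps[2:(n - 1)] > ps[1:(n - 2)] & ps[2:(n - 1)] > ps[3:n]) + 1
  pk <- pk[ps[pk] > max(ps) * 1e-4]
  dev <- fr[pk] %% 150
  expect_true(all(pmin(dev, 150 - dev) <= 10))

  # 4 Hz amplitude modulation shows up in the MPS temporal marginal
  w <- harmonicVocalization(12, f0 = 120, nHarmonics = 30, amRate = 4,
                            seed = 1)
  mg <- mpsMarginals(welchMps(spectrogram(w, trim = 0.05)))
  fm <- as.numeric(names(mg$temporal))
  pos <- fm > 0.5 & fm < 20
  expect_lt(abs(fm[pos][which.max(mg$temporal[pos])] - 4), 1)

  expect_error(harmonicVocalization(1, f0 = 5000, nHarmonics = 10),
               "Nyquist")
})

test_that("ensembles are seeded, sized and validated", {
  spec <- ensembleSpec("bg", nItems = 3, itemDuration = 30, seed = 5)
  e1 <- buildEnsemble(spec)
  expect_length(e1, 3)
  expect_equal(sum(vapply(e1, duration, numeric(1))), 90)
  e2 <- buildEnsemble(spec)
  expect_identical(lapply(e1, samples), lapply(e2, samples))
  expect_error(ensembleSpec("bg", nItems = 0, itemDuration = 1), "nItems")
  expect_equal(e1[[2]]@metadata$category, "bg")
})

test_that("all generator outputs are peak-normalized and finite", {
  for (w in list(whiteNoise(0.5, seed = 1),
                 powerLawSound(0.5, spectralSlope = -4, modExponent = 2,
                               seed = 1),
                 harmonicVocalization(0.5, f0 = 200, nHarmonics = 20,
                                      formantCenters = c(500, 1500),
                                      amRate = 8, seed = 1))) {
    expect_true(all(is.finite(samples(w))))
    expect_lte(max(abs(samples(w))), 0.99 + 1e-12)
  }
})
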