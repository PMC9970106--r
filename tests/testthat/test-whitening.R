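test_that("bandwidth gain follows the ERB law", {
  g <- bandwidthGain(c(100, 1000, 10000))
  expect_equal(g[1], 0)
  expect_equal(g[3], 10 * log10(erbBandwidth(10000) / erbBandwidth(100)),
               tolerance = 1e-12)
  expect_equal(g[3], 14.9, tolerance = 0.05)
  cfs <- cfGrid(cochlearSpec())
  expect_true(all(diff(bandwidthGain(cfs)) > 0))
})

test_that("bandwidth gain plus flat spectrum predicts the white-noise
           cochlear spectrum", {
  w <- whiteNoise(12, seed = 6)
  psF <- powerSpectrum(spectrogram(w, trim = 0.05))
  psC <- powerSpectrum(cochleogram(w, trim = 0.05))
  pr <- predictCochlearSpectrum(10 * log10(psF), attr(psF, "freqs"),
                                attr(psC, "freqs"), 10 * log10(psC))
  expect_lt(pr$meanAbsError, 1)
  # offset invariance: a global dB shift of the input changes nothing
  pr2 <- predictCochlearSpectrum(10 * log10(psF) + 6, attr(psF, "freqs"),
                                 attr(psC, "freqs"), 10 * log10(psC))
  expect_equal(pr2$predictedDb, pr$predictedDb, tolerance = 1e-9)
  expect_error(predictCochlearSpectrum(10 * log10(psF),
                                       attr(psF, "freqs"), c(50, 200)),
               "outside")
})

test_that("a declining synthetic sound is predicted within 1.5 dB", {
  w <- powerLawSound(20, spectralSlope = -3, modExponent = 1, seed = 7)
  psF <- powerSpectrum(spectrogram(w, trim = 0.05))
  psC <- powerSpectrum(cochleogram(w, trim = 0.05))
  pr <- predictCochlearSpectrum(10 * log10(psF), attr(psF, "freqs"),
                                attr(psC, "freqs"), 10 * log10(psC))
  expect_lt(pr$meanAbsError, 1.5)
})

test_that("modulation-bandwidth gain exactly cancels a 1/(fm omega) MPS", {
  fm <- seq(-1000, 1000 - 2 / 3, by = 2 / 3)
  om <- seq(0, 25, by = 0.148)
  P <- outer(fm, om, function(f, o) ifelse(f == 0 | o == 0, 0,
                                           1 / (abs(f) * o)))
  mps <- new("ModulationPowerSpectrum", power = P, fmAxis = fm,
             omegaAxis = om, omegaUnit = "cyc/oct", source = "cochlear",
             nSegments = 1)
  pr <- predictMidbrainMps(mps)
  expect_lt(diff(range(pr$predictedDb)), 1e-9)
  # gain arithmetic: doubling fm0 adds 10 log10(2) dB
  g <- pr$gainDb
  mm <- midbrainMps(mps)
  i1 <- which(fmAxis(mm) == 64); i2 <- which(fmAxis(mm) == 128)
  expect_equal(g[i2, 10] - g[i1, 10], 10 * log10(2), tolerance = 1e-9)

  # constant-Q integration flattens the same MPS within 3 dB (interior)
  M <- 10 * log10(mpsPower(mm))
  ii <- abs(fmAxis(mm)) >= 4 & abs(fmAxis(mm)) <= 256
  jj <- omegaAxis(mm) >= 0.2 & omegaAxis(mm) <= 2.5
  expect_lt(diff(range(M[ii, jj])), 3)
  # and the prediction matches the constant-Q computation within 3 dB
  pr2 <- predictMidbrainMps(mps, measured = mm)
  expect_lt(max(abs((pr2$predictedDb - M)[ii, jj] -
                    mean((pr2$predictedDb - M)[ii, jj]))), 3)
})

test_that("Greenwood map: inverse identity, counts and octave gain", {
  map <- greenwoodMap()
  f35 <- map$A * (10^(map$a * 35) - map$k)
  expect_equal(greenwoodPosition(f35), 35, tolerance = 1e-9)
  expect_equal(greenwoodPosition(40), 0.83, tolerance = 0.01)
  expect_error(greenwoodPosition(5), "outside")

  expect_lt(abs(hairCellCount(20, 40) - 80) / 80, 0.05)
  expect_lt(abs(hairCellCount(10000, 20000) - 500) / 500, 0.05)
  expect_lt(abs(hairCellGainDb(c(20, 40), c(10000, 20000)) - 8), 0.3)
  expect_equal(hairCellGainDb(c(20, 40), c(20, 40)), 0)
  expect_equal(hairCellGainDb(c(100, 200), c(1000, 2000)),
               -hairCellGainDb(c(1000, 2000), c(100, 200)),
               tolerance = 1e-9)

  # octave-band counts are monotone and telescope to density x length
  bands <- 20 * 2^(0:10)
  counts <- vapply(seq_len(10), function(i)
    hairCellCount(bands[i], bands[i + 1]), numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_equal(sum(counts),
               map$density * (greenwoodPosition(bands[11]) -
                              greenwoodPosition(bands[1])),
               tolerance = 5)
})
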