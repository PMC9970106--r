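# Welch MPS estimator, power contours and marginals, exercised mostly on
# small synthetic envelope fields built directly in code.

ripple_cochleogram <- function(f0, o0, a = 0.3, dur = 6, nx = 664) {
  cs <- cochlearSpec()
  xo <- log2(cfGrid(cs) / 100)[seq_len(nx)]
  t <- (0:(dur * 2000 - 1)) / 2000
  make_cochleogram(1 + a * cos(2 * pi * outer(t * f0, xo * o0, "+")))
}

test_that("a constant input concentrates all power at the origin", {
  cg <- make_cochleogram(matrix(2, 4000, 300))
  # rectangular window: DFT bins are orthogonal to a constant
  m <- welchMps(cg, kaiserBeta = 0, demean = "none")
  P <- mpsPower(m)
  i0 <- which(fmAxis(m) == 0)
  expect_equal(sum(P[-i0, ]) / P[i0, 1], 0, tolerance = 1e-15)
  expect_equal(sum(P[i0, -1]) / P[i0, 1], 0, tolerance = 1e-15)
})

test_that("a ripple is recovered at its modulation coordinates", {
  m <- welchMps(ripple_cochleogram(16, 1.13))
  P <- mpsPower(m)
  pk <- which(P == max(P), arr.ind = TRUE)
  expect_lt(abs(abs(fmAxis(m)[pk[1]]) - 16), 1 / 1.5 + 1e-9)  # one fm bin
  expect_lt(abs(omegaAxis(m)[pk[2]] - 1.13), 0.15 + 1e-9)     # one bin
  mg <- mpsMarginals(m)
  fm <- as.numeric(names(mg$temporal))
  expect_lt(abs(abs(fm[which.max(mg$temporal)]) - 16), 1)
})

test_that("marginals are unit-sum and recover separable factors", {
  m <- welchMps(ripple_cochleogram(8, 0.8))
  mg <- mpsMarginals(m)
  expect_equal(sum(mg$temporal), 1, tolerance = 1e-9)
  expect_equal(sum(mg$spectral), 1, tolerance = 1e-9)

  # separable product MPS built directly: marginals return the factors
  fm <- seq(-100, 99, by = 1); om <- seq(0, 20, by = 0.5)
  pf <- exp(-abs(fm) / 20); po <- exp(-om / 5)
  mps <- new("ModulationPowerSpectrum", power = outer(pf, po),
             fmAxis = fm, omegaAxis = om, omegaUnit = "cyc/oct",
             source = "cochlear", nSegments = 1)
  mg <- mpsMarginals(mps)
  expect_equal(unname(mg$temporal), pf / sum(pf), tolerance = 1e-12)
  expect_equal(unname(mg$spectral), po / sum(po), tolerance = 1e-12)
})

test_that("power contour matches a brute-force quantile oracle", {
  fm <- seq(-50, 49, by = 1); om <- seq(0, 10, by = 0.25)
  P <- outer(exp(-fm^2 / (2 * 8^2)), exp(-om^2 / (2 * 2^2)))
  mps <- new("ModulationPowerSpectrum", power = P, fmAxis = fm,
             omegaAxis = om, omegaUnit = "cyc/oct", source = "cochlear",
             nSegments = 1)
  ct <- powerContour(mps, 0.9)
  # oracle: sort bins, accumulate to 90%, take the extents of that set
  v <- sort(as.vector(P), decreasing = TRUE)
  thr <- v[which(cumsum(v) >= 0.9 * sum(v))[1]]
  sel <- which(P >= thr, arr.ind = TRUE)
  expect_equal(ct$fmMax, max(abs(fm[sel[, 1]])))
  expect_equal(ct$omegaMax, max(om[sel[, 2]]))

  # fraction = 1 spans the full extents
  ct1 <- powerContour(mps, 1)
  expect_equal(ct1$fmMax, 50)
  expect_equal(ct1$omegaMax, 10)

  # single-bin MPS: extents at that bin for any fraction
  P1 <- matrix(0, length(fm), length(om)); P1[60, 21] <- 1
  m1 <- new("ModulationPowerSpectrum", power = P1, fmAxis = fm,
            omegaAxis = om, omegaUnit = "cyc/oct", source = "cochlear",
            nSegments = 1)
  for (fr in c(0.1, 0.9)) {
    ct <- powerContour(m1, fr)
    expect_equal(ct$fmMax, abs(fm[60]))
    expect_equal(ct$omegaMax, om[21])
  }
  expect_error(powerContour(new("ModulationPowerSpectrum",
                                power = matrix(0, 2, 2),
                                fmAxis = c(-1, 0), omegaAxis = c(0, 1),
                                omegaUnit = "cyc/oct", source = "cochlear",
                                nSegments = 1)), "no power")
})

test_that("rectangular-window MPS satisfies Parseval within 1%", {
  set.seed(3)
  V <- matrix(abs(rnorm(6000 * 200)) + 1, 6000, 200)
  cg <- make_cochleogram(V)
  m <- welchMps(cg, kaiserBeta = 0, demean = "none")
  dz <- diff(fmAxis(m))[1]; dg <- diff(omegaAxis(m))[1]
  wcol <- c(1, rep(2, length(omegaAxis(m)) - 1))
  total <- sum(sweep(mpsPower(m), 2, wcol, "*")) * dz * dg
  expect_equal(total, mean(V[1:6000, ]^2), tolerance = 0.01)
})

test_that("Welch averaging reduces per-bin scatter as 1/sqrt(N)", {
  set.seed(8)
  mk <- function(nt) make_cochleogram(
    matrix(abs(rnorm(nt * 150)) + 0.5, nt, 150))
  rel_se <- function(m) {
    P <- mpsPower(m)
    keep <- abs(fmAxis(m)) > 5 & abs(fmAxis(m)) < 500
    sd(P[keep, 3]) / mean(P[keep, 3])
  }
  r1 <- rel_se(welchMps(mk(3000 * 4), demean = "none", kaiserBeta = 0))
  r2 <- rel_se(welchMps(mk(3000 * 16), demean = "none", kaiserBeta = 0))
  expect_equal(r1 / r2, 2, tolerance = 0.35)
})

test_that("inputs shorter than one segment are refused", {
  cg <- make_cochleogram(matrix(1, 1000, 50))
  expect_error(welchMps(cg), "shorter than one")
})

test_that("unit tags are enforced across representations", {
  w <- whiteNoise(2, seed = 5)
  mf <- welchMps(spectrogram(w, trim = 0.05))
  expect_equal(omegaUnit(mf), "cyc/kHz")
  expect_equal(mpsSource(mf), "fourier")
  mc <- welchMps(cochleogram(w, trim = 0.05))
  expect_equal(omegaUnit(mc), "cyc/oct")
  # cross-unit arithmetic is refused
  expect_error(midbrainMps(mf), "cyc/oct")
  ct <- powerContour(mf)
  expect_error(modulationEntropy(mc, ct), "units")
})
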