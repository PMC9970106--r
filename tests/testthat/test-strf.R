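# Constant-Q STRF filterbank: secondary parameters, MTFs, kernels, and the
# equivalence of the time-domain and modulation-domain output power routes.

test_that("secondary parameters follow the Q = 1 design formulas", {
  p <- strfSecondaryParams(512, 1)
  expect_equal(p$tau, sqrt(sqrt(2) - 1) / (pi * 512), tolerance = 1e-12)
  expect_equal(p$tau * 1000, 0.40, tolerance = 0.01)
  expect_equal(p$bw, 2 * sqrt(2 * log(2)) / pi, tolerance = 1e-12)
  expect_equal(p$bw, 0.750, tolerance = 0.001)
  expect_error(strfSecondaryParams(0, 1), "non-zero")
  expect_error(strfSecondaryParams(4, 0), "positive")
})

test_that("the filter grid is octave-spaced and sign-symmetric", {
  g <- strfGrid()
  expect_length(g$fm0Values, 66)             # 33 magnitudes per direction
  expect_length(g$omega0Values, 52)
  expect_equal(g$fm0Values, -rev(g$fm0Values))
  expect_equal(range(abs(g$fm0Values)), c(2, 512))
  expect_equal(min(g$omega0Values), 0.1)
  expect_lte(max(g$omega0Values), 3.6)
  # multiplicative spacing
  mags <- abs(g$fm0Values[g$fm0Values > 0])
  expect_equal(diff(log2(mags)), rep(0.25, 32), tolerance = 1e-12)
  expect_equal(diff(log2(g$omega0Values)), rep(0.1, 51), tolerance = 1e-12)
})

test_that("MTF peaks at the best modulation frequencies with unit gain", {
  fm <- seq(-200, 200, by = 0.25)
  om <- seq(0, 4, by = 0.005)
  m <- strfMtf(64, 0.5, fm, om)
  expect_equal(max(m), 1, tolerance = 1e-3)
  pk <- which(m == max(m), arr.ind = TRUE)
  expect_lt(abs(fm[pk[1]] - 64), 0.5)
  expect_lt(abs(om[pk[2]] - 0.5), 0.01)
  # reflection symmetry of real kernels: |MTF| of -fm0 is the fm-mirror
  m2 <- strfMtf(-64, 0.5, rev(-fm), om)
  expect_equal(unclass(m2)[nrow(m2):1, ], unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("modulation bandwidths scale with the best frequencies (Q = 1)", {
  # temporal bandwidth read at the half-power point of |MTF|, spectral at
  # the half-amplitude point: the conventions under which the design
  # constants give unit quality factor on each axis
  g <- strfGrid()
  for (f0 in abs(g$fm0Values[g$fm0Values > 0])[seq(1, 33, by = 4)]) {
    z <- seq(-4 * f0, 4 * f0, length.out = 4001)
    mt <- strfMtf(f0, 1, z, 1)
    s <- z[mt >= 1 / sqrt(2)]
    expect_equal((max(s) - min(s)) / f0, 1, tolerance = 0.05)
  }
  for (o0 in g$omega0Values[seq(1, 52, by = 6)]) {
    gm <- seq(max(0, o0 - 2 * o0), o0 + 2 * o0, length.out = 4001)
    ms <- strfMtf(32, o0, 32, gm)
    s <- gm[ms >= 0.5]
    expect_equal((max(s) - min(s)) / o0, 1, tolerance = 0.05)
  }
})

test_that("sampled kernels are causal, oriented, and unit-peak in the MTF", {
  k <- strfKernel(16, 0.5)
  expect_equal(k[1, ], numeric(ncol(k)))     # alpha envelope zero at t = 0
  # measured peak |MTF| of the sampled kernel
  nt <- 2^ceiling(log2(nrow(k) * 4)); nx <- 2^ceiling(log2(ncol(k) * 4))
  for (spec in list(k, strfKernel(-16, 0.5), strfKernel(64, 2))) {
    Kp <- matrix(0, nt, nx)
    Kp[seq_len(nrow(spec)), seq_len(ncol(spec))] <- spec
    pk <- max(Mod(fft(Kp))) * attr(spec, "dt") * attr(spec, "dx")
    expect_equal(pk, 1, tolerance = 0.02)
  }
  # sign flip mirrors the spectro-temporal orientation
  k2 <- strfKernel(-16, 0.5)
  expect_equal(unclass(k2), unclass(k)[, ncol(k):1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(strfKernel(512, 1, envFs = 2000), "envFs")
  expect_error(strfKernel(16, 3.6, xStep = 0.2), "xStep")
})

test_that("a matched ripple passes with unity gain; DC is rejected", {
  cs <- cochlearSpec()
  xo <- log2(cfGrid(cs) / 100)
  t <- (0:(8 * 2000 - 1)) / 2000
  a <- 0.3
  V <- 1 + a * cos(2 * pi * outer(t * 16, xo * 1.13, "+"))
  cg <- make_cochleogram(V)
  sm <- midbrainFilterOutput(cg, 16, 1.13)
  st <- attr(sm, "settle")
  expect_equal(mean(sm[st:nrow(sm), ]^2), a^2 / 2, tolerance = 0.05)

  # constant cochleogram: band-pass STRFs pass almost nothing; the
  # closed-form |MTF(0,0)|^2 is ~5e-4 for this filter, plus edge leakage
  # outside the fully-supported channels
  smc <- midbrainFilterOutput(make_cochleogram(matrix(1, 6000, 664)),
                              16, 1.13)
  mtf00 <- strfMtf(16, 1.13, 0, 0)[1, 1]
  expect_lt(mtf00, 0.05)
  expect_lt(mean(smc[st:nrow(smc), attr(smc, "validX")]^2), 4 * mtf00^2)

  # linearity
  sm2 <- midbrainFilterOutput(make_cochleogram(2 * V), 16, 1.13)
  expect_equal(sm2, 2 * sm, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("time-domain and modulation-domain routes agree (Parseval)", {
  # stationary synthetic field; filters whose kernels are fully resolved
  # and fit inside the represented octave range
  V <- make_stationary_field(30 * 2000, 664, seed = 42)
  cg <- make_cochleogram(V)
  mmod <- midbrainMps(welchMps(cg))
  Vd <- sweep(V, 2, colMeans(V))
  sub <- expand.grid(fm0 = c(4, 16, 64, -32), omega0 = c(1.13, 2.26))
  pt <- pm <- numeric(nrow(sub))
  for (r in seq_len(nrow(sub))) {
    sm <- audmod:::.strf_filter_matrix(Vd, 2000, 0.01, sub$fm0[r],
                                       sub$omega0[r])
    st <- attr(sm, "settle")
    pt[r] <- mean(sm[st:nrow(sm), attr(sm, "validX")]^2)
    i <- which.min(abs(fmAxis(mmod) - sub$fm0[r]))
    j <- which.min(abs(omegaAxis(mmod) - sub$omega0[r]))
    pm[r] <- mpsPower(mmod)[i, j]
  }
  expect_true(all(abs(pt / pm - 1) <= 0.10))
  expect_lt(abs(sum(pt) / sum(pm) - 1), 0.02)
})

test_that("a single ripple drives the nearest midbrain grid filter most", {
  cs <- cochlearSpec()
  xo <- log2(cfGrid(cs) / 100)
  t <- (0:(8 * 2000 - 1)) / 2000
  V <- 1 + 0.4 * cos(2 * pi * outer(t * 22.6, xo * 0.8, "+"))
  mm <- midbrainMps(welchMps(make_cochleogram(V)))
  pk <- which(mpsPower(mm) == max(mpsPower(mm)), arr.ind = TRUE)
  expect_lt(abs(log2(abs(fmAxis(mm)[pk[1]]) / 22.6)), 0.25)
  expect_lt(abs(log2(omegaAxis(mm)[pk[2]] / 0.8)), 0.1)
})
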