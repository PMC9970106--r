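# Shared fixtures. The white-noise calibration at study scale (3 x 90 s)
# is expensive, so it is computed once on first use and cached for the
# whole test run.

.fixture_env <- new.env(parent = emptyenv())

get_calibration <- function() {
  if (is.null(.fixture_env$calib))
    .fixture_env$calib <- whiteNoiseCalibration(seeds = 1:3, noiseDur = 90)
  .fixture_env$calib
}

# small synthetic cochleogram-like container built directly from a matrix
make_cochleogram <- function(V, frameRate = 2000) {
  cs <- cochlearSpec()
  cfs <- cfGrid(cs)[seq_len(ncol(V))]
  new("Cochleogram", values = V, frameRate = frameRate,
      channelFreqs = cfs, channelOctaves = log2(cfs / 100),
      spec = unclass(cs))
}

# stationary synthetic envelope field: positive offset plus lightly
# smoothed iid noise (spectrally almost flat in both dimensions)
make_stationary_field <- function(nt, nx, seed = 42, offset = 5) {
  set.seed(seed)
  V <- matrix(rnorm(nt * nx), nt, nx)
  V <- stats::filter(V, rep(1, 3) / 3)
  V <- t(stats::filter(t(V), rep(1, 3) / 3))
  V[is.na(V)] <- 0
  pmax(V + offset, 0)
}
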