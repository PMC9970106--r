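# Mechanistic whitening predictions: the bandwidth-dependent gain of the
# cochlear filterbank, its prediction of the cochlear output spectrum from
# the Fourier spectrum, the analogous modulation-bandwidth gain prediction
# of the midbrain MPS, and the Greenwood cochlear-map hair-cell gain.

#' Bandwidth-dependent gain of the cochlear filterbank
#'
#' A filter integrating a flat power spectrum over its ERB picks up power
#' proportional to the bandwidth, so the cochlear stage imposes a gain
#' 10 log10(b(f)) that rises with CF; reported relative to the first CF.
#'
#' @param cfs channel center frequencies in Hz.
#' @return numeric vector of gains in dB (first element 0).
#' @examples
#' g <- bandwidthGain(c(100, 10000))
#' g[2]  # ~14.9 dB
#' @export
bandwidthGain <- function(cfs) {
  if (any(cfs <= 0)) stop("cfs must be positive")
  g <- 10 * log10(erbBandwidth(cfs))
  g - g[1]
}

#' Predict the cochlear output spectrum from the Fourier spectrum
#'
#' Interpolates the Fourier dB spectrum at the cochlear CFs (linearly in
#' log frequency), adds the bandwidth gain, and aligns the prediction to
#' the measured cochlear spectrum by a least-squares additive offset.
#'
#' @param fourierDb Fourier power spectrum in dB.
#' @param fourierFreqs its channel frequencies in Hz (must cover the CFs).
#' @param cfs cochlear CFs in Hz.
#' @param measuredDb measured cochlear spectrum in dB at \code{cfs}
#'   (optional; enables offset alignment and the error summary).
#' @return list with \code{predictedDb} (offset-aligned when
#'   \code{measuredDb} is given), \code{gainDb}, and when available
#'   \code{meanAbsError} (dB).
#' @export
predictCochlearSpectrum <- function(fourierDb, fourierFreqs, cfs,
                                    measuredDb = NULL) {
  if (min(cfs) < min(fourierFreqs) || max(cfs) > max(fourierFreqs))
    stop("CFs outside the Fourier spectrum range")
  base <- approx(log(fourierFreqs), fourierDb, xout = log(cfs))$y
  gain <- bandwidthGain(cfs)
  pred <- base + gain
  out <- list(gainDb = gain)
  if (!is.null(measuredDb)) {
    off <- mean(measuredDb - pred)
    pred <- pred + off
    out$offsetDb <- off
    out$meanAbsError <- mean(abs(pred - measuredDb))
  }
  out$predictedDb <- pred
  out
}

#' Predict the midbrain MPS from the cochlear MPS
#'
#' Constant-Q midbrain filters integrate modulation power over bandwidths
#' proportional to |fm0| * omega0, adding a modulation-bandwidth gain
#' 10 log10(|fm0| * omega0) to the interpolated cochlear MPS (in dB). A
#' cochlear MPS falling as 1/(fm * omega) is therefore predicted flat.
#'
#' @param mpsC a cochlear-source \linkS4class{ModulationPowerSpectrum}.
#' @param grid an \code{\link{strfGrid}}.
#' @param measured a midbrain \linkS4class{ModulationPowerSpectrum} to
#'   align against (optional).
#' @return list with \code{predictedDb} (matrix over the grid),
#'   \code{gainDb}, and when \code{measured} is given \code{meanAbsError}
#'   in dB.
#' @export
predictMidbrainMps <- function(mpsC, grid = strfGrid(), measured = NULL) {
  stopifnot(is(mpsC, "ModulationPowerSpectrum"))
  if (omegaUnit(mpsC) != "cyc/oct")
    stop("cochlear MPS must have cyc/oct units")
  P <- mpsPower(mpsC)
  P[P <= 0] <- NA
  zeta <- fmAxis(mpsC); gm <- omegaAxis(mpsC)
  # bilinear interpolation of the dB surface in (log |fm|, log omega),
  # separately for upward and downward temporal modulations
  base <- matrix(NA_real_, length(grid$fm0Values),
                 length(grid$omega0Values))
  for (sgn in c(-1, 1)) {
    zi <- which(sign(zeta) == sgn & abs(zeta) > 0)
    zi <- zi[order(abs(zeta[zi]))]
    gi <- which(gm > 0)
    dbP <- 10 * log10(P[zi, gi, drop = FALSE])
    rows <- which(sign(grid$fm0Values) == sgn)
    at_g <- t(apply(dbP, 1, function(r)
      .lininterp(log(gm[gi]), r, log(grid$omega0Values))))
    base[rows, ] <- apply(at_g, 2, function(cl)
      .lininterp(log(abs(zeta[zi])), cl,
                 log(abs(grid$fm0Values[rows]))))
  }
  gain <- outer(10 * log10(abs(grid$fm0Values)),
                10 * log10(grid$omega0Values), "+")
  pred <- base + gain
  out <- list(gainDb = gain)
  if (!is.null(measured)) {
    md <- 10 * log10(mpsPower(measured))
    off <- mean(md - pred, na.rm = TRUE)
    pred <- pred + off
    out$offsetDb <- off
    out$meanAbsError <- mean(abs(pred - md), na.rm = TRUE)
  }
  out$predictedDb <- pred
  out
}

# interpolation with linear extrapolation beyond the axis edges (approx
# rule = 2 would clamp, biasing filters below the first modulation bin)
.lininterp <- function(x, y, xout) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(rep(if (length(y)) y else NA_real_,
                                length(xout)))
  out <- approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1]
  if (any(lo))
    out[lo] <- y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xout[lo] - x[1])
  n <- length(x)
  hi <- xout > x[n]
  if (any(hi))
    out[hi] <- y[n] + (y[n] - y[n - 1]) / (x[n] - x[n - 1]) *
      (xout[hi] - x[n])
  out
}

#' Greenwood frequency-position map of the human cochlea
#'
#' f(x) = A (10^(a x) - k) with the canonical human constants; positions
#' are millimeters from the apex.
#'
#' @param A,a,k Greenwood constants (165.4 Hz, 0.06 /mm, 0.88).
#' @param length cochlear length in mm (35).
#' @param density hair cells per mm (100).
#' @return list of class "CochlearMap".
#' @export
greenwoodMap <- function(A = 165.4, a = 0.06, k = 0.88, length = 35,
                         density = 100) {
  structure(list(A = A, a = a, k = k, length = length, density = density),
            class = "CochlearMap")
}

#' Cochlear position of a frequency under the Greenwood map
#'
#' Inverse map x = (1/a) log10(f/A + k), in mm from the apex.
#'
#' @param f frequency in Hz (vectorized).
#' @param map a \code{\link{greenwoodMap}}.
#' @return position(s) in mm.
#' @export
greenwoodPosition <- function(f, map = greenwoodMap()) {
  fmin <- map$A * (1 - map$k)
  fmax <- map$A * (10^(map$a * map$length) - map$k)
  if (any(f <= fmin) || any(f > fmax))
    stop(sprintf("f outside the mapped range (%.3g, %.5g] Hz", fmin, fmax))
  (1 / map$a) * log10(f / map$A + map$k)
}

#' Hair cells between two frequencies
#'
#' Hair-cell density times the cochlear distance between the band edges,
#' rounded to the nearest integer.
#'
#' @param fLo,fHi band edges in Hz, fLo < fHi.
#' @param map a \code{\link{greenwoodMap}}.
#' @return integer hair-cell count.
#' @examples
#' hairCellCount(20, 40)        # ~80
#' hairCellCount(10000, 20000)  # ~500
#' @export
hairCellCount <- function(fLo, fHi, map = greenwoodMap()) {
  if (fLo >= fHi) stop("fLo must be below fHi")
  round(map$density *
        (greenwoodPosition(fHi, map) - greenwoodPosition(fLo, map)))
}

#' Output-power gain from hair-cell density between two bands
#'
#' Under power summation across receptors, a band with more hair cells
#' gains 10 log10(count ratio) dB; the highest octave of human hearing
#' gains about 8 dB over the lowest.
#'
#' @param bandLo,bandHi two-element Hz vectors (reference band, target
#'   band).
#' @param map a \code{\link{greenwoodMap}}.
#' @return gain in dB of bandHi over bandLo.
#' @export
hairCellGainDb <- function(bandLo, bandHi, map = greenwoodMap()) {
  nLo <- hairCellCount(bandLo[1], bandLo[2], map)
  nHi <- hairCellCount(bandHi[1], bandHi[2], map)
  if (nLo == 0 || nHi == 0) stop("zero hair-cell count in a band")
  10 * log10(nHi / nLo)
}
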