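# Spectral and modulation entropy, spectrum slope fitting and ensemble
# slope standardization.

#' Per-channel power spectrum of an envelope representation
#'
#' Time-mean of the squared envelope values per channel, restricted to
#' channels with center frequencies inside \code{range}.
#'
#' @param x a \linkS4class{Cochleogram} or \linkS4class{AudSpectrogram}.
#' @param range frequency range in Hz to keep (default 100 - 10000).
#' @return named numeric vector of channel powers, with attributes
#'   \code{freqs} (Hz) and \code{axis} ("octave" or "kHz").
#' @export
powerSpectrum <- function(x, range = c(100, 10000)) {
  stopifnot(is(x, "TimeFreqRepresentation"))
  f <- channelFreqs(x)
  keep <- f >= range[1] & f <= range[2]
  p <- colMeans(envValues(x)[, keep, drop = FALSE]^2)
  structure(p, freqs = f[keep],
            axis = if (is(x, "Cochleogram")) "octave" else "kHz")
}

#' Normalized spectral entropy of a channel power distribution
#'
#' The unit-sum normalized power spectrum is treated as a probability
#' distribution; its Shannon entropy is divided by the capacity log2(N) of
#' the N-filter decomposition, so 1 means a perfectly whitened (flat)
#' output and 0 a single active channel.
#'
#' @param power non-negative per-channel power (e.g. from
#'   \code{\link{powerSpectrum}}).
#' @return list with \code{entropy} (normalized, 0-1), \code{rawEntropy}
#'   (bits), \code{nChannels} and the unit-sum spectrum \code{pbar}.
#' @export
spectralEntropy <- function(power) {
  if (any(power < 0)) stop("power must be non-negative")
  if (sum(power) <= 0) stop("power is all zero")
  pbar <- power / sum(power)
  H <- -sum(ifelse(pbar > 0, pbar * log2(pbar), 0))
  list(entropy = H / log2(length(pbar)), rawEntropy = H,
       nChannels = length(pbar), pbar = pbar)
}

#' Total and marginal modulation entropy of an MPS
#'
#' Restricts the MPS to |fm| <= fmMax and omega <= omegaMax, normalizes the
#' restricted power to unit sum and computes the Shannon entropy divided by
#' log2(L * M), where L and M are the numbers of spectral and temporal
#' modulation bins retained. Marginal entropies are normalized by log2(L)
#' and log2(M). The restriction range is taken from the white-noise 90%
#' power contour (Fourier/cochlear) or the physiological caps of 500 Hz
#' and 4 cycles/octave (midbrain).
#'
#' @param mps a \linkS4class{ModulationPowerSpectrum}.
#' @param fmMax,omegaMax restriction bounds, in the MPS axis units; a
#'   "ModulationRange" from \code{\link{powerContour}} may be given as
#'   \code{fmMax}.
#' @return list with \code{entropy} (H_M), \code{spectralMarginal} (H_SM),
#'   \code{temporalMarginal} (H_TM), bin counts \code{L}, \code{M} and the
#'   bounds used.
#' @export
modulationEntropy <- function(mps, fmMax, omegaMax = NULL) {
  if (inherits(fmMax, "ModulationRange")) {
    if (fmMax$omegaUnit != omegaUnit(mps))
      stop("range units (", fmMax$omegaUnit, ") do not match MPS units (",
           omegaUnit(mps), ")")
    omegaMax <- fmMax$omegaMax
    fmMax <- fmMax$fmMax
  }
  ri <- abs(fmAxis(mps)) <= fmMax
  ci <- omegaAxis(mps) <= omegaMax
  if (!any(ri) || !any(ci)) stop("empty restriction")
  P <- mpsPower(mps)[ri, ci, drop = FALSE]
  if (sum(P) <= 0) stop("restricted MPS has no power")
  M <- nrow(P); L <- ncol(P)
  pb <- P / sum(P)
  Hof <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))
  list(entropy = Hof(pb) / log2(L * M),
       spectralMarginal = Hof(colSums(pb)) / log2(L),
       temporalMarginal = Hof(rowSums(pb)) / log2(M),
       L = L, M = M, fmMax = fmMax, omegaMax = omegaMax)
}

#' Linear fit to a dB power spectrum on its native frequency axis
#'
#' Ordinary least squares of 10 log10(power) against frequency in kHz
#' (Fourier representations) or octaves above 100 Hz (cochlear), over
#' channels inside \code{range} (0.1 - 10 kHz).
#'
#' @param power per-channel power with a \code{freqs} attribute, as
#'   returned by \code{\link{powerSpectrum}}, or a plain vector with
#'   \code{freqs} given.
#' @param axis "kHz" or "octave"; defaults to the attribute on
#'   \code{power}.
#' @param freqs channel frequencies in Hz if not attached to \code{power}.
#' @param range fit range in Hz.
#' @return list of class "SlopeFit" with slope (dB/kHz or dB/octave),
#'   intercept (dB) and the axis used.
#' @export
fitSpectrumSlope <- function(power, axis = NULL, freqs = NULL,
                             range = c(100, 10000)) {
  if (is.null(freqs)) freqs <- attr(power, "freqs")
  if (is.null(axis)) axis <- attr(power, "axis") %||% "kHz"
  keep <- freqs >= range[1] & freqs <= range[2] & power > 0
  if (sum(keep) < 2) stop("need at least two positive channels in range")
  xv <- if (axis == "octave") log2(freqs[keep] / 100) else freqs[keep] / 1000
  yv <- 10 * log10(power[keep])
  cf <- coef(lm(yv ~ xv))
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 axis = axis, n = sum(keep)),
            class = "SlopeFit")
}

#' Standardize an ensemble of spectrum slopes
#'
#' Divides each slope by the ensemble (sample, n - 1) standard deviation so
#' the standardized distribution has unit SD, making slope spreads
#' comparable across filterbanks with different native axes.
#'
#' @param slopes numeric vector of slopes, or list of "SlopeFit" objects.
#' @return numeric vector of standardized slopes.
#' @export
standardizeSlopes <- function(slopes) {
  if (is.list(slopes)) slopes <- vapply(slopes, `[[`, numeric(1), "slope")
  if (length(slopes) < 2) stop("need at least two slopes")
  s <- sd(slopes)
  if (s == 0) stop("zero ensemble standard deviation")
  slopes / s
}
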