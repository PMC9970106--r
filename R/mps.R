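# Welch-averaged modulation power spectra of spectrogram-like inputs, the
# white-noise power contour used to bound entropy integration, and MPS
# marginals.

.mps_dx <- function(x) {
  if (is(x, "Cochleogram")) {
    list(dx = x@spec$cfStep, unit = "cyc/oct", source = "cochlear")
  } else {
    list(dx = x@spec$channelSpacing / 1000, unit = "cyc/kHz",
         source = "fourier")
  }
}

#' Welch-averaged modulation power spectrum
#'
#' The input envelope matrix is partitioned in time into adjacent
#' non-overlapping segments of \code{segmentDur} seconds; each segment is
#' weighted by a separable two-dimensional Kaiser window (temporal extent
#' \code{segmentDur}, spectral extent the full channel range), 2D Fourier
#' transformed, magnitude-squared and averaged. Values are power densities
#' per (Hz x omega-unit): with a rectangular window (\code{kaiserBeta = 0})
#' and \code{demean = FALSE} the density integrates to the time-frequency
#' mean square of the input. The temporal modulation axis is signed; the
#' spectral modulation axis keeps the non-negative half (for real inputs
#' the other half is its mirror image).
#'
#' @param x a \linkS4class{Cochleogram} or \linkS4class{AudSpectrogram}.
#' @param segmentDur Welch segment duration in seconds (default 1.5).
#' @param kaiserBeta Kaiser window shape parameter (default 3.4).
#' @param demean DC handling per segment before the transform:
#'   \code{"channel"} (default) removes each channel's window-weighted
#'   temporal mean, so the MPS describes temporal modulations only (the
#'   time-averaged spectral profile is the domain of the spectral entropy,
#'   and its fm = 0 ridge would otherwise dominate the power contour);
#'   \code{"global"} removes only the overall segment mean;
#'   \code{"none"} keeps everything, leaving the envelope DC at (0, 0).
#' @return A \linkS4class{ModulationPowerSpectrum}.
#' @export
welchMps <- function(x, segmentDur = 1.5, kaiserBeta = 3.4,
                     demean = c("channel", "global", "none")) {
  stopifnot(is(x, "TimeFreqRepresentation"))
  if (isTRUE(demean)) demean <- "channel"
  demean <- match.arg(demean)
  V <- envValues(x)
  dt <- 1 / frameRate(x)
  ax <- .mps_dx(x)
  seg <- round(segmentDur * frameRate(x))
  nseg <- floor(nrow(V) / seg)
  if (nseg < 1)
    stop(sprintf("input (%.3g s) shorter than one %.3g s segment",
                 nrow(V) * dt, segmentDur))
  nx <- ncol(V)
  wt <- .kaiser(seg, kaiserBeta)
  wx <- .kaiser(nx, kaiserBeta)
  W <- outer(wt, wx)
  sw2 <- sum(W^2)
  # zero-pad the channel dimension to a smooth composite length: the FFT
  # runs fast and the spectral-modulation grid lands on round values
  # (0.1 cyc/kHz for the 991-channel Fourier bank)
  nxp <- .good_fft_size(nx)
  P <- matrix(0, seg, nxp)
  pad <- matrix(0, seg, nxp - nx)
  for (s in seq_len(nseg)) {
    Sn <- V[((s - 1) * seg + 1):(s * seg), , drop = FALSE]
    if (demean == "channel")
      Sn <- sweep(Sn, 2, colSums(Sn * wt) / sum(wt))
    WS <- W * Sn
    if (demean == "global") WS <- WS - (sum(WS) / sum(W)) * W
    P <- P + Mod(fft(cbind(WS, pad)))^2
  }
  P <- P * (dt * ax$dx / (sw2 * nseg))
  # reorder rows to signed fm, keep non-negative omega columns
  kf <- seq(0, seg - 1)
  fm <- ifelse(kf > seg / 2, kf - seg, kf) / (seg * dt)
  of <- order(fm)
  half <- floor(nxp / 2)
  omega <- (0:half) / (nxp * ax$dx)
  new("ModulationPowerSpectrum", power = P[of, 1:(half + 1), drop = FALSE],
      fmAxis = fm[of], omegaAxis = omega, omegaUnit = ax$unit,
      source = ax$source, nSegments = nseg)
}

.good_fft_size <- function(n) {
  ok <- function(m) {
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    m == 1
  }
  while (!ok(n)) n <- n + 1
  n
}

.kaiser <- function(n, beta) {
  if (n == 1) return(1)
  k <- 0:(n - 1)
  besselI(beta * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2)), 0) /
    besselI(beta, 0)
}

#' Power contour of a modulation power spectrum
#'
#' Finds the smallest power threshold whose super-level set contains at
#' least \code{fraction} of the total power, and returns the bounding
#' extents of that set: the maximum |fm| and maximum omega it reaches.
#' Computed on white noise, these extents define the modulation range used
#' for entropy integration.
#'
#' @param mps a \linkS4class{ModulationPowerSpectrum}.
#' @param fraction power fraction in (0, 1]; the analysis default is 0.9.
#' @return list of class "ModulationRange" with fmMax, omegaMax (in the
#'   units of the MPS axes), threshold and fraction.
#' @export
powerContour <- function(mps, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  P <- mpsPower(mps)
  total <- sum(P)
  if (total <= 0) stop("MPS has no power")
  v <- sort(as.vector(P), decreasing = TRUE)
  thr <- v[which(cumsum(v) >= fraction * total)[1]]
  sel <- P >= thr
  structure(list(fmMax = max(abs(fmAxis(mps)[rowSums(sel) > 0])),
                 omegaMax = max(omegaAxis(mps)[colSums(sel) > 0]),
                 threshold = thr, fraction = fraction,
                 omegaUnit = omegaUnit(mps)),
            class = "ModulationRange")
}

#' Marginal distributions of a modulation power spectrum
#'
#' Sums power over the other axis and normalizes each marginal to unit sum.
#'
#' @param mps a \linkS4class{ModulationPowerSpectrum}.
#' @return list with \code{temporal} (over fm, named by fm) and
#'   \code{spectral} (over omega).
#' @export
mpsMarginals <- function(mps) {
  P <- mpsPower(mps)
  tm <- rowSums(P); sm <- colSums(P)
  list(temporal = stats::setNames(tm / sum(tm), signif(fmAxis(mps), 8)),
       spectral = stats::setNames(sm / sum(sm), signif(omegaAxis(mps), 8)))
}
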