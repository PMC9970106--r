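# Mid-level (auditory midbrain) filterbank: Gabor-alpha spectro-temporal
# receptive fields whose modulation bandwidths scale with their best
# modulation frequencies (constant Q = 1), their modulation transfer
# functions, and the midbrain modulation power spectrum computed either by
# filtering the cochleogram (time domain) or by weighting the cochleogram
# MPS with the squared MTFs (modulation domain; the two are related by
# Parseval's theorem).

#' Secondary STRF parameters from the tuning contract
#'
#' The temporal decay tau and spectral spread bw are tied to the best
#' modulation frequencies so the measured 3 dB modulation bandwidths equal
#' the best modulation frequencies (quality factor 1):
#' tau = sqrt(sqrt(2) - 1) / (pi |fm0|), bw = 2 sqrt(2 ln 2) / (pi omega0).
#'
#' @param fm0 best temporal modulation frequency, Hz (signed, non-zero).
#' @param omega0 best spectral modulation frequency, cycles/octave (> 0).
#' @return list with tau (s) and bw (octaves).
#' @examples
#' strfSecondaryParams(512, 1)$tau * 1000  # ~0.40 ms
#' @export
strfSecondaryParams <- function(fm0, omega0) {
  if (any(fm0 == 0) || any(omega0 <= 0))
    stop("fm0 must be non-zero and omega0 positive")
  list(tau = sqrt(sqrt(2) - 1) / (pi * abs(fm0)),
       bw = 2 * sqrt(2 * log(2)) / (pi * omega0))
}

# Fourier transforms of the separable STRF factors.
# temporal alpha envelope (t/tau) exp(-(t - tau)/tau) u(t):
#   A(v) = e * tau / (1 + i 2 pi v tau)^2
# spectral Gaussian exp(-2 x^2 / bw^2):
#   G(v) = bw sqrt(pi/2) exp(-pi^2 v^2 bw^2 / 2)
.strf_At <- function(v, tau) exp(1) * tau / (1 + 2i * pi * v * tau)^2
.strf_Gx <- function(v, bw) bw * sqrt(pi / 2) * exp(-pi^2 * v^2 * bw^2 / 2)

.strf_peak <- function(fm0, omega0, phase = 0) {
  p <- strfSecondaryParams(fm0, omega0)
  Mod(exp(1i * phase) * .strf_At(0, p$tau) * .strf_Gx(0, p$bw) +
      exp(-1i * phase) * .strf_At(2 * fm0, p$tau) *
        .strf_Gx(2 * omega0, p$bw)) / 2
}

#' Constant-Q STRF filter grid
#'
#' Best temporal modulation frequencies at quarter-octave steps between
#' \code{fmMin} and \code{fmMax} Hz for both directions (signed fm0), and
#' best spectral modulations at tenth-octave steps between \code{omegaMin}
#' and \code{omegaMax} cycles/octave.
#'
#' @param fmMin,fmMax temporal grid edges in Hz (default 2 and 512).
#' @param fmStep temporal step in octaves (default 0.25).
#' @param omegaMin,omegaMax spectral grid edges in cycles/octave.
#' @param omegaStep spectral step in octaves (default 0.1).
#' @return list of class "STRFGrid" with fm0Values (signed, ascending),
#'   omega0Values and a data.frame \code{filters} of all combinations with
#'   tau and bw.
#' @export
strfGrid <- function(fmMin = 2, fmMax = 512, fmStep = 0.25,
                     omegaMin = 0.1, omegaMax = 3.6, omegaStep = 0.1) {
  mags <- fmMin * 2^(seq(0, log2(fmMax / fmMin) + 1e-9, by = fmStep))
  fm0 <- c(-rev(mags), mags)
  om0 <- omegaMin * 2^(seq(0, log2(omegaMax / omegaMin) + 1e-9,
                           by = omegaStep))
  filters <- expand.grid(fm0 = fm0, omega0 = om0)
  sp <- strfSecondaryParams(filters$fm0, filters$omega0)
  filters$tau <- sp$tau
  filters$bw <- sp$bw
  structure(list(fm0Values = fm0, omega0Values = om0, filters = filters),
            class = "STRFGrid")
}

#' Modulation transfer function of one STRF (closed form)
#'
#' Magnitude of the 2D Fourier transform of the Gabor-alpha STRF on the
#' given modulation axes, normalized to unit peak gain. The peak sits at
#' (fm0, omega0) and the 3 dB widths equal |fm0| and omega0 (Q = 1).
#'
#' @param fm0,omega0 best modulation frequencies (Hz, cycles/octave).
#' @param fm,omega evaluation axes (Hz, cycles/octave; omega may be signed).
#' @param phase STRF phase in radians (default 0).
#' @return matrix |MTF| of dim length(fm) x length(omega), with attribute
#'   \code{center = c(fm0, omega0)}.
#' @export
strfMtf <- function(fm0, omega0, fm, omega, phase = 0) {
  p <- strfSecondaryParams(fm0, omega0)
  m1 <- exp(1i * phase) *
    outer(.strf_At(fm - fm0, p$tau), .strf_Gx(omega - omega0, p$bw))
  m2 <- exp(-1i * phase) *
    outer(.strf_At(fm + fm0, p$tau), .strf_Gx(omega + omega0, p$bw))
  structure(Mod(m1 + m2) / (2 * .strf_peak(fm0, omega0, phase)),
            center = c(fm0, omega0))
}

#' Sampled Gabor-alpha STRF kernel
#'
#' STRF(t, x) = A (t/tau) exp(-(t - tau)/tau) exp(-2 x^2 / bw^2)
#' cos(2 pi omega0 x + 2 pi fm0 t + phase) u(t), sampled on the
#' cochleogram grid and amplitude-normalized so the measured peak |MTF|
#' (2D FFT of the sampled kernel) is 1.
#'
#' @param fm0,omega0 best modulation frequencies.
#' @param envFs temporal sampling rate in Hz; at least 8 samples per
#'   carrier period are required (envFs >= 8 |fm0|), otherwise an error
#'   names the required rate.
#' @param xStep spectral sampling step in octaves (likewise
#'   xStep <= 1 / (8 omega0)).
#' @param phase STRF phase in radians.
#' @return matrix (time x octave) with attributes \code{t}, \code{x}
#'   (sample positions; x is centered on 0) and \code{dt}, \code{dx}.
#' @export
strfKernel <- function(fm0, omega0, envFs = 2000, xStep = 0.01, phase = 0) {
  if (envFs < 8 * abs(fm0))
    stop(sprintf("under-resolved kernel: need envFs >= %g Hz", 8 * abs(fm0)))
  if (xStep > 1 / (8 * omega0))
    stop(sprintf("under-resolved kernel: need xStep <= %.4g oct",
                 1 / (8 * omega0)))
  p <- strfSecondaryParams(fm0, omega0)
  t <- seq(0, 15 * p$tau, by = 1 / envFs)
  nh <- floor(2.5 * p$bw / xStep)
  x <- xStep * (-nh:nh)                 # symmetric about x = 0
  env_t <- (t / p$tau) * exp(-(t - p$tau) / p$tau)
  env_x <- exp(-2 * x^2 / p$bw^2)
  K <- outer(env_t, env_x) *
    cos(2 * pi * omega0 * rep(x, each = length(t)) +
        2 * pi * fm0 * rep(t, times = length(x)) + phase)
  # normalize so the measured peak |MTF| of the sampled kernel is 1
  nt <- 2^ceiling(log2(length(t) * 4))
  nx <- 2^ceiling(log2(length(x) * 4))
  Kp <- matrix(0, nt, nx)
  Kp[seq_along(t), seq_along(x)] <- K
  peak <- max(Mod(fft(Kp))) * (1 / envFs) * xStep
  structure(K / peak, t = t, x = x, dt = 1 / envFs, dx = xStep,
            fm0 = fm0, omega0 = omega0, peakNorm = 1 / peak)
}

#' Filter a cochleogram with one STRF (time-domain route)
#'
#' Two-dimensional convolution of the sampled STRF kernel with the
#' cochleogram (causal in time; zero-padded at the spectral edges, so
#' kernels wider than the represented octave range are truncated).
#'
#' @param c a \linkS4class{Cochleogram}.
#' @param fm0,omega0 best modulation frequencies of the filter.
#' @param phase STRF phase in radians.
#' @return matrix of filter output S_M with the cochleogram's dimensions,
#'   with attribute \code{settle} = number of initial frames covering the
#'   kernel duration (startup transient).
#' @export
midbrainFilterOutput <- function(c, fm0, omega0, phase = 0) {
  stopifnot(is(c, "Cochleogram"))
  .strf_filter_matrix(envValues(c), frameRate(c), c@spec$cfStep,
                      fm0, omega0, phase)
}

# The Gabor-alpha kernel is separable: K(t, x) = Re[a(t) b(x)] with
# a(t) = (t/tau) e^{-(t-tau)/tau} e^{i(2 pi fm0 t + phase)} and
# b(x) = e^{-2x^2/bw^2} e^{i 2 pi omega0 x}, so the 2D convolution splits
# into two chunked 1D convolutions (much cheaper than a full 2D FFT).
.strf_filter_matrix <- function(V, envFs, xs, fm0, omega0, phase = 0) {
  K <- strfKernel(fm0, omega0, envFs = envFs, xStep = xs, phase = phase)
  if (nrow(K) > nrow(V)) stop("kernel longer than cochleogram")
  p <- strfSecondaryParams(fm0, omega0)
  tg <- attr(K, "t"); xg <- attr(K, "x")
  a <- (tg / p$tau) * exp(-(tg - p$tau) / p$tau) *
    exp(1i * (2 * pi * fm0 * tg + phase)) * attr(K, "peakNorm")
  b <- exp(-2 * xg^2 / p$bw^2) * exp(1i * 2 * pi * omega0 * xg)
  nxk <- length(xg); ntk <- length(tg)
  xoff <- (nxk - 1) / 2

  # 1D convolution along x (rows independent; chunk over time)
  nxf <- .good_fft_size(ncol(V) + nxk - 1)
  Fb <- fft(c(b, complex(real = numeric(nxf - nxk))))
  Z <- matrix(0i, nrow(V), ncol(V))
  step <- max(1, floor(4e6 / nxf))
  for (r0 in seq(1, nrow(V), by = step)) {
    rr <- r0:min(r0 + step - 1, nrow(V))
    block <- cbind(V[rr, , drop = FALSE],
                   matrix(0, length(rr), nxf - ncol(V)))
    cv <- t(mvfft(mvfft(t(block)) * Fb, inverse = TRUE)) / nxf
    Z[rr, ] <- cv[, round(xoff) + seq_len(ncol(V)), drop = FALSE]
  }

  # 1D causal convolution along t (columns independent; chunk over x)
  ntf <- .good_fft_size(nrow(V) + ntk - 1)
  Fa <- fft(c(a, complex(real = numeric(ntf - ntk))))
  out <- matrix(0, nrow(V), ncol(V))
  cstep <- max(1, floor(4e6 / ntf))
  for (c0 in seq(1, ncol(V), by = cstep)) {
    cc <- c0:min(c0 + cstep - 1, ncol(V))
    block <- rbind(Z[, cc, drop = FALSE],
                   matrix(0i, ntf - nrow(V), length(cc)))
    cv <- mvfft(mvfft(block) * Fa, inverse = TRUE) / ntf
    out[, cc] <- Re(cv[seq_len(nrow(V)), , drop = FALSE])
  }
  out <- out * attr(K, "dt") * attr(K, "dx")
  # channels whose spectral kernel support lies fully inside the
  # represented octave range (no edge truncation)
  vx <- seq_len(ncol(V))
  vx <- vx[vx > xoff & vx <= ncol(V) - xoff]
  structure(out, settle = ntk, validX = vx)
}

#' Midbrain modulation power spectrum
#'
#' Mean-square output power of every filter in a constant-Q STRF grid. Two
#' routes: \code{"modulation"} integrates the cochleogram MPS against the
#' squared closed-form MTFs (fast; the default), \code{"time"} convolves
#' each sampled STRF with the cochleogram and averages the squared output
#' over the settled region (slow; useful for validation). By Parseval's
#' theorem the two agree for stationary inputs.
#'
#' @param x a cochleogram-source \linkS4class{ModulationPowerSpectrum}
#'   (route "modulation") or a \linkS4class{Cochleogram} (route "time").
#' @param grid an \code{\link{strfGrid}}.
#' @param route "modulation" or "time".
#' @param demean time route only: remove each channel's temporal mean
#'   before filtering (default TRUE), matching the DC convention of the
#'   Welch cochleogram MPS. Output power is averaged over the temporally
#'   settled region and, where the kernel fits inside the octave range,
#'   over the fully-supported channels.
#' @return A \linkS4class{ModulationPowerSpectrum} with source "midbrain";
#'   axes are the (log-spaced) grid centers and values are mean-square
#'   filter outputs.
#' @export
midbrainMps <- function(x, grid = strfGrid(),
                        route = c("modulation", "time"), demean = TRUE) {
  route <- match.arg(route)
  fm0 <- grid$fm0Values
  om0 <- grid$omega0Values
  if (route == "modulation") {
    stopifnot(is(x, "ModulationPowerSpectrum"))
    if (mpsSource(x) != "cochlear" || omegaUnit(x) != "cyc/oct")
      stop("modulation route needs a cochleogram MPS in cyc/oct units")
    zeta <- fmAxis(x); gamma <- omegaAxis(x)
    dz <- zeta[2] - zeta[1]; dg <- gamma[2] - gamma[1]
    # full-plane integration: the stored half-plane represents gamma > 0
    # bins twice (conjugate symmetry), except a Nyquist column
    wcol <- c(1, rep(2, length(gamma) - 1))
    Mw <- sweep(mpsPower(x), 2, wcol, "*") * dz * dg
    taus <- strfSecondaryParams(fm0, 1)$tau
    Ac <- sapply(seq_along(fm0),
                 function(i) .strf_At(zeta - fm0[i], taus[i]))
    U <- Mod(Ac)^2
    Aflip <- Ac[, rev(seq_along(fm0))]    # A(zeta + fm0) = A1 of -fm0
    Ct <- Re(Ac * Conj(Aflip))
    bws <- strfSecondaryParams(1, om0)$bw
    V1 <- sapply(seq_along(om0),
                 function(j) .strf_Gx(gamma - om0[j], bws[j])^2)
    V2 <- sapply(seq_along(om0),
                 function(j) .strf_Gx(gamma + om0[j], bws[j])^2)
    Cx <- sapply(seq_along(om0),
                 function(j) .strf_Gx(gamma - om0[j], bws[j]) *
                             .strf_Gx(gamma + om0[j], bws[j]))
    P <- 0.25 * (crossprod(U, Mw %*% V1) +
                 crossprod(U[, rev(seq_along(fm0))], Mw %*% V2) +
                 2 * crossprod(Ct, Mw %*% Cx))
    A2 <- vapply(seq_along(fm0),
                 function(i) .strf_At(2 * fm0[i], taus[i]), complex(1))
    G2 <- vapply(seq_along(om0),
                 function(j) .strf_Gx(2 * om0[j], bws[j]), numeric(1))
    pk <- (outer(exp(1) * taus, .strf_Gx(0, bws)) + outer(A2, G2)) / 2
    P <- P / Mod(pk)^2
    nseg <- x@nSegments
  } else {
    stopifnot(is(x, "Cochleogram"))
    V <- envValues(x)
    if (demean) V <- sweep(V, 2, colMeans(V))
    P <- matrix(0, length(fm0), length(om0))
    for (j in seq_along(om0)) for (i in seq_along(fm0)) {
      sm <- .strf_filter_matrix(V, frameRate(x), x@spec$cfStep,
                                fm0[i], om0[j])
      st <- attr(sm, "settle")
      vx <- attr(sm, "validX")
      if (!length(vx)) vx <- seq_len(ncol(sm))
      P[i, j] <- mean(sm[st:nrow(sm), vx]^2)
    }
    nseg <- 0
  }
  P[P < 0] <- 0
  new("ModulationPowerSpectrum", power = unname(as.matrix(P)), fmAxis = fm0,
      omegaAxis = om0, omegaUnit = "cyc/oct", source = "midbrain",
      nSegments = nseg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
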