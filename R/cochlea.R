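# Cochlear stage: ERB-scaled gammatone filterbank, Hilbert envelopes and a
# B-spline synaptic lowpass, producing the cochleogram.

#' Cochlear filterbank specification
#'
#' Characteristic frequencies are spaced logarithmically at \code{cfStep}
#' octaves, starting one step above \code{fMin}: cf_k = fMin * 2^(cfStep*k)
#' for k = 1, 2, ... up to \code{fMax} (664 channels with the defaults).
#'
#' @param fMin,fMax CF range in Hz.
#' @param cfStep CF spacing in octaves.
#' @param order gammatone filter order n (default 4, the standard
#'   auditory-nerve fit).
#' @param fs waveform sampling rate the filterbank operates at, Hz.
#' @param synapticCutoff -3 dB cutoff of the synaptic lowpass, Hz.
#' @param envFs output envelope sampling rate, Hz.
#' @return list with class "cochlearSpec".
#' @export
cochlearSpec <- function(fMin = 100, fMax = 10000, cfStep = 0.01, order = 4,
                         fs = 44100, synapticCutoff = 750, envFs = 2000) {
  stopifnot(fMin > 0, fMin < fMax, fMax <= fs / 2, cfStep > 0, order >= 1,
            synapticCutoff < envFs / 2)
  structure(list(fMin = fMin, fMax = fMax, cfStep = cfStep,
                 order = as.integer(order), fs = fs,
                 synapticCutoff = synapticCutoff, envFs = envFs),
            class = "cochlearSpec")
}

#' Characteristic-frequency grid of the cochlear filterbank
#'
#' @param spec a \code{\link{cochlearSpec}}.
#' @return numeric vector of CFs in Hz (664 for the default spec).
#' @examples
#' length(cfGrid(cochlearSpec()))  # 664
#' @export
cfGrid <- function(spec = cochlearSpec()) {
  kmax <- floor(log2(spec$fMax / spec$fMin) / spec$cfStep + 1e-9)
  spec$fMin * 2^(spec$cfStep * seq_len(kmax))
}

#' Equivalent rectangular bandwidth (ERB) of the cochlear filter at f
#'
#' b(f) = 24.7 * (4.37 * f/1000 + 1) Hz.
#'
#' @param f frequency in Hz (vectorized, must be >= 0).
#' @return bandwidth in Hz.
#' @examples
#' erbBandwidth(1000)  # 132.6 Hz
#' @export
erbBandwidth <- function(f) {
  if (any(f < 0)) stop("f must be non-negative")
  24.7 * (4.37 * f / 1000 + 1)
}

# analytic (complex) gammatone impulse response t^(n-1) exp(-2 pi b t)
# exp(i 2 pi f t); duration chosen so the truncated envelope-energy tail
# is below `tail`.
.gammatone_length <- function(cf, order, tail = 1e-6) {
  b <- erbBandwidth(cf)
  qgamma(1 - tail, shape = 2 * order - 1, rate = 4 * pi * b)
}

.gammatone_analytic <- function(cf, fs, order = 4, len = NULL) {
  if (is.null(len)) len <- .gammatone_length(cf, order)
  t <- seq(0, len, by = 1 / fs)
  h <- t^(order - 1) * exp(-2 * pi * erbBandwidth(cf) * t) *
    exp(1i * 2 * pi * cf * t)
  list(t = t, h = h)
}

#' Sampled gammatone impulse response
#'
#' h(t) = A t^(n-1) cos(2 pi cf t) exp(-2 pi b(cf) t) for t >= 0, with the
#' gain A normalized numerically so the peak magnitude of the frequency
#' response is 1 (unity maximum gain).
#'
#' @param cf characteristic frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param order gammatone order n.
#' @param len length in seconds; the default covers the envelope until the
#'   truncated tail energy is below 1e-6 of the total. If a shorter
#'   \code{len} is given an error names the required length.
#' @return numeric vector of samples, with attributes \code{t} (times),
#'   \code{gain} (A) and \code{cf}.
#' @export
gammatoneImpulseResponse <- function(cf, fs, order = 4, len = NULL) {
  need <- .gammatone_length(cf, order)
  if (!is.null(len) && len < need)
    stop(sprintf("len too short: tail energy exceeds 1e-6; need >= %.4g s",
                 need))
  ga <- .gammatone_analytic(cf, fs, order, len)
  h <- Re(ga$h)
  nfft <- 2^ceiling(log2(max(length(h) * 4, 4096)))
  A <- 1 / max(abs(fft(c(h, numeric(nfft - length(h))))))
  structure(h * A, t = ga$t, gain = A, cf = cf, order = order, fs = fs)
}

#' Time-frequency resolution of a gammatone filter
#'
#' Second-moment widths of the energy-normalized impulse-response envelope
#' and transfer-function magnitude squared: sigma_t about the envelope
#' energy centroid (the group delay), sigma_f about the spectral centroid;
#' Delta-t = 2 sigma_t, Delta-f = 2 sigma_f. All gammatone filters sit
#' strictly above the uncertainty bound Delta-t * Delta-f >= 1/pi.
#'
#' @param cf characteristic frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param order gammatone order.
#' @return list with deltaT, deltaF (s, Hz), groupDelay (s) and
#'   uncertaintyProduct.
#' @export
filterResolution <- function(cf, fs, order = 4) {
  ga <- .gammatone_analytic(cf, fs, order)
  e2 <- Mod(ga$h)^2
  e2 <- e2 / sum(e2)
  mu_t <- sum(ga$t * e2)
  sigma_t <- sqrt(sum((ga$t - mu_t)^2 * e2))
  nfft <- 2^ceiling(log2(max(length(e2) * 8, 8192)))
  H2 <- Mod(fft(c(ga$h, complex(real = numeric(nfft - length(ga$h))))))^2
  f <- (0:(nfft - 1)) * fs / nfft
  keep <- f <= fs / 2          # analytic response lives at positive f
  H2 <- H2[keep]; f <- f[keep]
  H2 <- H2 / sum(H2)
  mu_f <- sum(f * H2)
  sigma_f <- sqrt(sum((f - mu_f)^2 * H2))
  list(deltaT = 2 * sigma_t, deltaF = 2 * sigma_f, groupDelay = mu_t,
       uncertaintyProduct = 4 * sigma_t * sigma_f)
}

# Time scale of the cubic B-spline synaptic kernel: the kernel is the
# 4-fold convolution of a width-delta box, transfer sinc(f delta)^4, and
# delta is set so the -3 dB point falls at the cutoff.
.bspline_delta <- function(cutoff) {
  f <- function(x) (sin(pi * x) / (pi * x))^4 - 1 / sqrt(2)
  uniroot(f, c(1e-6, 0.5), tol = 1e-12)$root / cutoff
}

#' Compute the cochleogram of a waveform
#'
#' Per channel: gammatone bandpass filtering (implemented as an analytic
#' complex-gammatone recursion whose output magnitude is the Hilbert
#' envelope of the real filter output), then a cubic B-spline synaptic
#' lowpass with -3 dB cutoff \code{spec$synapticCutoff}, resampled to
#' \code{spec$envFs}. Small negative lowpass outputs are clipped to zero.
#'
#' @param w a \linkS4class{Waveform} with \code{sampleRate(w) == spec$fs}.
#' @param spec a \code{\link{cochlearSpec}}.
#' @param trim seconds discarded at each edge of the output (filter
#'   transients); default 0 keeps the full duration.
#' @return A \linkS4class{Cochleogram}.
#' @export
cochleogram <- function(w, spec = cochlearSpec(), trim = 0) {
  stopifnot(is(w, "Waveform"))
  if (length(samples(w)) == 0) stop("empty waveform")
  if (abs(sampleRate(w) - spec$fs) > 1e-9)
    stop(sprintf("waveform fs (%g) does not match spec fs (%g)",
                 sampleRate(w), spec$fs))
  cfs <- cfGrid(spec)
  n_off <- round(trim * spec$fs)
  n_out <- floor((duration(w) - 2 * trim) * spec$envFs)
  if (n_out < 1) stop("trim removes the whole cochleogram")
  vals <- .gammatone_cochleogram_cpp(samples(w), spec$fs, cfs,
                                     erbBandwidth(cfs), spec$order,
                                     .bspline_delta(spec$synapticCutoff),
                                     spec$envFs, n_out, n_off)
  new("Cochleogram", values = vals, frameRate = spec$envFs,
      channelFreqs = cfs, channelOctaves = log2(cfs / spec$fMin),
      spec = unclass(spec))
}
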