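# Constant-resolution Gabor (short-term Fourier) filterbank. Each channel
# is a complex Gabor filter with a Gaussian window; envelope magnitudes are
# returned on the same frame grid as the cochleogram so downstream
# modulation code is shared.

#' Gabor filterbank specification from its two-sigma bandwidth
#'
#' The Gaussian window standard deviation is set so the energy-density
#' second-moment widths satisfy Delta-f = 2 sigma_f (and hence
#' Delta-t = 1/(pi Delta-f), the Gabor equality case of the uncertainty
#' bound Delta-t * Delta-f = 1/pi).
#'
#' @param deltaF two-sigma bandwidth in Hz (the analysis resolutions are 30, 120 and 480).
#' @param channelSpacing channel spacing in Hz (default 10).
#' @param frameRate output frame rate in Hz (default 2000).
#' @param fMin,fMax channel center-frequency range in Hz.
#' @return list of class "gaborSpec" with sigma (s), deltaT (s) and the
#'   grid parameters.
#' @examples
#' gaborSpec(30)$deltaT * 1000  # 10.6 ms
#' @export
gaborSpec <- function(deltaF = 30, channelSpacing = 10, frameRate = 2000,
                      fMin = 100, fMax = 10000) {
  stopifnot(deltaF > 0, channelSpacing > 0, fMin < fMax)
  sigma <- 1 / (sqrt(2) * pi * deltaF)
  structure(list(deltaF = deltaF, sigma = sigma, deltaT = 1 / (pi * deltaF),
                 channelSpacing = channelSpacing, frameRate = frameRate,
                 fMin = fMin, fMax = fMax),
            class = "gaborSpec")
}

#' 3 dB (half-power) bandwidth of a Gabor channel
#'
#' Full width at half maximum of the Gaussian power transfer function:
#' sqrt(2 ln 2) * deltaF (141.3 Hz for deltaF = 120).
#'
#' @param spec a \code{\link{gaborSpec}}.
#' @return bandwidth in Hz.
#' @export
threeDbBandwidth <- function(spec) {
  sqrt(2 * log(2)) * spec$deltaF
}

#' Numerically measured time-frequency resolution of a Gabor filterbank
#'
#' Second-moment widths of the sampled window energy density and its
#' transfer-function magnitude squared; for Gaussian windows the product
#' Delta-t * Delta-f equals 1/pi to within discretization error.
#'
#' @param spec a \code{\link{gaborSpec}}.
#' @param fs sampling rate used to discretize the window.
#' @return list with deltaT, deltaF and uncertaintyProduct.
#' @export
gaborResolution <- function(spec, fs = 44100) {
  t <- seq(-6 * spec$sigma, 6 * spec$sigma, by = 1 / fs)
  w2 <- exp(-t^2 / spec$sigma^2)                # |w(t)|^2
  w2 <- w2 / sum(w2)
  sigma_t <- sqrt(sum(t^2 * w2))
  nfft <- 2^ceiling(log2(length(t) * 64))
  W2 <- Mod(fft(c(exp(-t^2 / (2 * spec$sigma^2)), numeric(nfft - length(t)))))^2
  f <- (0:(nfft - 1)) * fs / nfft
  f[f > fs / 2] <- f[f > fs / 2] - fs
  W2 <- W2 / sum(W2)
  sigma_f <- sqrt(sum(f^2 * W2))
  list(deltaT = 2 * sigma_t, deltaF = 2 * sigma_f,
       uncertaintyProduct = 4 * sigma_t * sigma_f)
}

#' Compute a constant-resolution Gabor spectrogram
#'
#' Envelope magnitude of each complex Gabor channel, with unity peak
#' transfer gain per channel (a steady tone of amplitude a at a channel
#' center yields channel magnitude a). Channels are evaluated exactly in
#' the frequency domain: the waveform spectrum is weighted by the Gaussian
#' transfer function of each channel and the analytic channel signal is
#' reconstructed directly at the output frame rate.
#'
#' @param w a \linkS4class{Waveform}; \code{sampleRate(w)} must be at least
#'   twice \code{spec$fMax}.
#' @param spec a \code{\link{gaborSpec}}.
#' @param trim seconds discarded at each edge of the output (default 0).
#' @return An \linkS4class{AudSpectrogram}.
#' @export
spectrogram <- function(w, spec = gaborSpec(), trim = 0) {
  stopifnot(is(w, "Waveform"))
  fs <- sampleRate(w)
  if (fs < 2 * spec$fMax) stop("sampling rate below 2 * fMax")
  fr <- spec$frameRate
  g <- .gcd(round(fs), round(fr))
  blk <- round(fs) / g                         # pad so frames align exactly
  x <- samples(w)
  N <- ceiling(length(x) / blk) * blk
  M <- N * fr / fs
  j0 <- round(trim * fr)
  n_frames <- floor((length(x) / fs - 2 * trim) * fr)
  if (n_frames < 1) stop("trim removes the whole spectrogram")
  S <- fft(c(x, numeric(N - length(x))))
  sigma_f <- spec$deltaF / 2
  fc <- seq(spec$fMin, spec$fMax, by = spec$channelSpacing)
  vals <- matrix(0, n_frames, length(fc))
  df <- fs / N
  for (j in seq_along(fc)) {
    i_lo <- max(0, ceiling((fc[j] - 6 * sigma_f) / df))
    i_hi <- min(floor((fc[j] + 6 * sigma_f) / df), floor(N / 2))
    idx <- i_lo:i_hi
    gw <- 2 * exp(-((idx * df - fc[j])^2) / (4 * sigma_f^2))
    y <- complex(real = numeric(M))
    y[(idx %% M) + 1] <- gw * S[idx + 1]
    z <- fft(y, inverse = TRUE) / N
    vals[, j] <- Mod(z)[j0 + seq_len(n_frames)]
  }
  new("AudSpectrogram", values = vals, frameRate = fr, channelFreqs = fc,
      spec = unclass(spec))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
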