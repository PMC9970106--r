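# Seeded synthetic-sound generators. These stand in for natural recording
# ensembles: power spectra that decline with frequency (negative dB/kHz
# slopes), 1/f^a envelope-modulation spectra, harmonic vocalization
# surrogates, and Gaussian white noise as the reference control.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(expr)
}

.peak_normalize <- function(x, peak = 0.99) {
  m <- max(abs(x))
  if (m > 0) x * (peak / m) else x
}

#' Gaussian white noise reference sound
#'
#' Zero-mean Gaussian samples; the long-run Fourier power spectrum is flat
#' (0 dB/kHz slope), which makes white noise the calibration reference for
#' entropy ranges. Output is peak-normalized to |x| <= 0.99.
#'
#' @param duration length in seconds.
#' @param fs sampling rate in Hz (default 44100).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A \linkS4class{Waveform}.
#' @examples
#' w <- whiteNoise(0.5, seed = 1)
#' @export
whiteNoise <- function(duration, fs = 44100, seed = 1) {
  if (duration <= 0) stop("duration must be positive")
  if (fs <= 0) stop("fs must be positive")
  x <- .with_seed(seed, rnorm(round(duration * fs)))
  Waveform(.peak_normalize(x), fs,
           metadata = list(category = "white_noise", seed = seed))
}

# Hermitian half-spectrum synthesis: given target amplitude per positive
# frequency bin and random phases, return a real signal of length n.
.synth_from_magnitude <- function(mag_fun, n, fs, phases) {
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(ceiling(n / 2))          # positive-frequency bins
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  amp <- mag_fun(freqs[half])
  spec[half] <- amp * exp(1i * phases[seq_along(half)])
  spec[n - half + 2] <- Conj(spec[half])
  Re(fft(spec, inverse = TRUE)) / n
}

#' Power-law spectrum sound with 1/f^a envelope modulations
#'
#' Frequency-domain synthesis of a noise carrier whose Fourier power
#' spectrum follows a straight line in dB per kHz over the synthesis band
#' (50 Hz - 11 kHz), multiplied by a positive slow envelope whose
#' modulation power decays as fm^(-modExponent) over 0.3 - 200 Hz. The
#' combination emulates the first-order spectrum and modulation statistics
#' of natural sound recordings.
#'
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param spectralSlope target Fourier power-spectrum slope in dB/kHz
#'   (0 = white over the synthesis band).
#' @param modExponent exponent a >= 0 of the 1/fm^a envelope-modulation
#'   power spectrum; 0 gives a flat (unmodulated beyond noise) envelope.
#' @param seed integer seed.
#' @param modDepth standard deviation of the zero-mean modulator added to
#'   the unit carrier envelope (default 0.75; the modulator is clipped so
#'   the envelope stays non-negative).
#' @return A \linkS4class{Waveform}.
#' @export
powerLawSound <- function(duration, fs = 44100, spectralSlope = 0,
                          modExponent = 0, seed = 1, modDepth = 0.75) {
  if (duration <= 0) stop("duration must be positive")
  if (modExponent < 0) stop("modExponent must be >= 0")
  n <- round(duration * fs)
  if (abs(spectralSlope) * 10 > 200)
    warning("requested slope exceeds the representable dynamic range; ",
            "output is best effort")
  x <- .with_seed(seed, {
    nb <- length(2:ceiling(n / 2))
    ph_c <- runif(nb, 0, 2 * pi)
    ph_m <- runif(nb, 0, 2 * pi)
    carrier <- .synth_from_magnitude(function(f) {
      ifelse(f >= 50 & f <= 11000, 10^(spectralSlope * (f / 1000) / 20), 0)
    }, n, fs, ph_c)
    env <- 1
    if (modExponent >= 0) {
      g <- .synth_from_magnitude(function(f) {
        ifelse(f >= 0.3 & f <= 200, f^(-modExponent / 2), 0)
      }, n, fs, ph_m)
      if (sd(g) > 0) g <- g / sd(g)
      env <- pmax(0, 1 + modDepth * g)
    }
    carrier * env
  })
  Waveform(.peak_normalize(x), fs,
           metadata = list(category = "power_law", seed = seed,
                           spectralSlope = spectralSlope,
                           modExponent = modExponent))
}

#' Harmonic vocalization surrogate
#'
#' A harmonic stack at multiples of f0 with a formant-shaped spectral
#' envelope (Lorentzian resonances, 20% relative bandwidth) and optional
#' sinusoidal amplitude modulation, emulating voiced vocalizations.
#' Without formants, harmonic amplitudes fall as 1/k.
#'
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param f0 fundamental frequency, Hz.
#' @param nHarmonics number of harmonics (all below Nyquist, else error).
#' @param formantCenters numeric vector of formant center frequencies in
#'   Hz, or NULL for the default 1/k envelope.
#' @param amRate sinusoidal amplitude-modulation rate in Hz (0 = none).
#' @param amDepth modulation depth in (0, 1], default 0.5.
#' @param seed integer seed (randomizes harmonic phases).
#' @return A \linkS4class{Waveform}.
#' @export
harmonicVocalization <- function(duration, fs = 44100, f0 = 120,
                                 nHarmonics = 30, formantCenters = NULL,
                                 amRate = 0, amDepth = 0.5, seed = 1) {
  if (f0 <= 0) stop("f0 must be positive")
  if (nHarmonics < 1) stop("nHarmonics must be >= 1")
  if (nHarmonics * f0 >= fs / 2)
    stop("highest harmonic ", nHarmonics * f0, " Hz is at or above Nyquist")
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  k <- seq_len(nHarmonics)
  fk <- k * f0
  if (is.null(formantCenters)) {
    amp <- 1 / k
  } else {
    amp <- 0.05 + vapply(fk, function(f)
      sum(1 / (1 + ((f - formantCenters) / (0.2 * formantCenters))^2)),
      numeric(1))
  }
  ph <- if (nHarmonics > 1) .with_seed(seed, runif(nHarmonics, 0, 2 * pi))
        else 0
  x <- numeric(n)
  for (i in k) x <- x + amp[i] * cos(2 * pi * fk[i] * t + ph[i])
  if (amRate > 0)
    x <- x * (1 + amDepth * cos(2 * pi * amRate * t)) / (1 + amDepth)
  Waveform(.peak_normalize(x), fs,
           metadata = list(category = "harmonic", seed = seed, f0 = f0,
                           nHarmonics = nHarmonics, amRate = amRate))
}

#' Ensemble specification for synthetic sound categories
#'
#' @param category label for the ensemble.
#' @param nItems number of sounds (>= 1).
#' @param itemDuration duration of each sound in seconds; natural-sound
#'   categories are analyzed with a minimum total length of 90 s.
#' @param seed base integer seed; item i uses seed + i.
#' @param spectralSlope,modExponent power-law category parameters
#'   (ignored when f0 is given).
#' @param f0 fundamental in Hz for a harmonic category, or NULL.
#' @param ... further arguments passed to the item generator.
#' @return A list of class "EnsembleSpec".
#' @export
ensembleSpec <- function(category, nItems, itemDuration, seed = 1,
                         spectralSlope = -3, modExponent = 1, f0 = NULL,
                         ...) {
  if (nItems < 1) stop("nItems must be >= 1")
  if (itemDuration <= 0) stop("itemDuration must be positive")
  structure(list(category = category, nItems = as.integer(nItems),
                 itemDuration = itemDuration, seed = as.integer(seed),
                 spectralSlope = spectralSlope, modExponent = modExponent,
                 f0 = f0, extra = list(...)),
            class = "EnsembleSpec")
}

#' Build a synthetic sound ensemble
#'
#' Generates \code{nItems} seeded waveforms from an
#' \code{\link{ensembleSpec}}; the same spec always yields identical
#' ensembles. Category, seed and parameters are attached as metadata.
#'
#' @param spec an \code{\link{ensembleSpec}}.
#' @return list of \linkS4class{Waveform}s.
#' @export
buildEnsemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  lapply(seq_len(spec$nItems), function(i) {
    si <- spec$seed + i
    w <- if (!is.null(spec$f0)) {
      do.call(harmonicVocalization,
              c(list(duration = spec$itemDuration, f0 = spec$f0, seed = si),
                spec$extra))
    } else if (identical(spec$category, "white_noise")) {
      whiteNoise(spec$itemDuration, seed = si)
    } else {
      do.call(powerLawSound,
              c(list(duration = spec$itemDuration,
                     spectralSlope = spec$spectralSlope,
                     modExponent = spec$modExponent, seed = si),
                spec$extra))
    }
    w@metadata$category <- spec$category
    w@metadata$item <- i
    w
  })
}
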