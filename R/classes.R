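#' @import methods
#' @importFrom stats fft rnorm runif sd lm coef approx uniroot qgamma
#' @useDynLib audmod, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Waveform: a sampled mono pressure signal
#'
#' Container for a mono sound waveform with its sampling rate and optional
#' generator metadata (category, seed, synthesis parameters).
#'
#' @slot samples numeric vector of pressure samples (arbitrary units).
#' @slot fs sampling rate in Hz.
#' @slot metadata named list of provenance information.
#' @export
setClass("Waveform",
         representation(samples = "numeric", fs = "numeric",
                        metadata = "list"),
         prototype(metadata = list()))

setValidity("Waveform", function(object) {
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (length(object@samples) < 1)
    return("waveform must contain at least one sample")
  if (!all(is.finite(object@samples)))
    return("all samples must be finite")
  TRUE
})

#' Construct a Waveform
#'
#' @param samples numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param metadata optional named list attached to the object.
#' @return A \linkS4class{Waveform}.
#' @examples
#' w <- Waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1/8000)), fs = 8000)
#' duration(w)
#' @export
Waveform <- function(samples, fs, metadata = list()) {
  new("Waveform", samples = as.numeric(samples), fs = as.numeric(fs),
      metadata = metadata)
}

#' @rdname Waveform
#' @param object,x a Waveform.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname Waveform
#' @export
setMethod("samples", "Waveform", function(x) x@samples)

#' @rdname Waveform
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname Waveform
#' @export
setMethod("sampleRate", "Waveform", function(x) x@fs)

#' @rdname Waveform
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname Waveform
#' @export
setMethod("duration", "Waveform", function(x) length(x@samples) / x@fs)

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %.3f s at %g Hz (%d samples)\n",
              duration(object), object@fs, length(object@samples)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Time-frequency envelope representations
#'
#' Virtual parent of \linkS4class{Cochleogram} and
#' \linkS4class{AudSpectrogram}: a non-negative time x channel envelope
#' matrix sampled at \code{frameRate} frames per second, with channels at
#' \code{channelFreqs} Hz in increasing order.
#'
#' @slot values time x channel matrix of non-negative envelope values.
#' @slot frameRate frames per second of the time axis.
#' @slot channelFreqs channel center frequencies in Hz, increasing.
#' @export
setClass("TimeFreqRepresentation",
         representation("VIRTUAL", values = "matrix", frameRate = "numeric",
                        channelFreqs = "numeric"))

setValidity("TimeFreqRepresentation", function(object) {
  if (ncol(object@values) != length(object@channelFreqs))
    return("number of columns must match number of channels")
  if (is.unsorted(object@channelFreqs, strictly = TRUE))
    return("channels must be ordered by increasing frequency")
  if (any(object@values < 0))
    return("envelope values must be non-negative")
  TRUE
})

#' @rdname TimeFreqRepresentation
#' @param x a time-frequency representation.
#' @export
setGeneric("envValues", function(x) standardGeneric("envValues"))
#' @rdname TimeFreqRepresentation
#' @export
setMethod("envValues", "TimeFreqRepresentation", function(x) x@values)

#' @rdname TimeFreqRepresentation
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname TimeFreqRepresentation
#' @export
setMethod("frameRate", "TimeFreqRepresentation", function(x) x@frameRate)

#' @rdname TimeFreqRepresentation
#' @export
setGeneric("channelFreqs", function(x) standardGeneric("channelFreqs"))
#' @rdname TimeFreqRepresentation
#' @export
setMethod("channelFreqs", "TimeFreqRepresentation",
          function(x) x@channelFreqs)

#' Cochleogram: cochlear-model envelope representation
#'
#' Output of the gammatone filterbank, Hilbert envelope and synaptic
#' lowpass stages. The spectral axis is logarithmic: channel k sits at
#' \code{channelOctaves[k] = log2(cf_k / 100)} octaves above 100 Hz.
#'
#' @slot channelOctaves channel positions in octaves above 100 Hz.
#' @slot spec the \code{cochlearSpec()} list used to build it.
#' @export
setClass("Cochleogram", contains = "TimeFreqRepresentation",
         representation(channelOctaves = "numeric", spec = "list"))

#' @rdname Cochleogram
#' @param x a Cochleogram.
#' @export
setGeneric("channelOctaves", function(x) standardGeneric("channelOctaves"))
#' @rdname Cochleogram
#' @export
setMethod("channelOctaves", "Cochleogram", function(x) x@channelOctaves)

setMethod("show", "Cochleogram", function(object) {
  cat(sprintf(
    "Cochleogram: %d frames x %d channels (%.4g s at %g frames/s)\n",
    nrow(object@values), ncol(object@values),
    nrow(object@values) / object@frameRate, object@frameRate))
  cat(sprintf("  CFs %.4g - %.5g Hz (log-spaced, octave axis)\n",
              min(object@channelFreqs), max(object@channelFreqs)))
})

#' AudSpectrogram: constant-resolution Gabor spectrogram
#'
#' Envelope magnitudes of a Gaussian-window (Gabor) short-term Fourier
#' filterbank; channels are linearly spaced in Hz.
#'
#' @slot spec the \code{gaborSpec()} list used to build it.
#' @export
setClass("AudSpectrogram", contains = "TimeFreqRepresentation",
         representation(spec = "list"))

setMethod("show", "AudSpectrogram", function(object) {
  cat(sprintf(
    "AudSpectrogram: %d frames x %d channels (%.4g s at %g frames/s)\n",
    nrow(object@values), ncol(object@values),
    nrow(object@values) / object@frameRate, object@frameRate))
  cat(sprintf("  channels %g - %g Hz (linear), delta-f = %g Hz\n",
              min(object@channelFreqs), max(object@channelFreqs),
              object@spec$deltaF))
})

#' Modulation power spectrum
#'
#' Power over temporal modulation frequency \code{fm} (Hz, signed) and
#' spectral modulation frequency \code{omega} (non-negative), with the
#' spectral-modulation unit tied to the producing representation:
#' cycles/kHz for Fourier spectrograms, cycles/octave for cochleograms and
#' the midbrain filterbank. Values are power densities per unit
#' (Hz x omega-unit) for the Welch estimator, or mean-square filter output
#' power for the midbrain source.
#'
#' @slot power matrix over (fm, omega).
#' @slot fmAxis temporal modulation frequencies, Hz (signed).
#' @slot omegaAxis spectral modulation frequencies, non-negative.
#' @slot omegaUnit "cyc/kHz" or "cyc/oct".
#' @slot source "fourier", "cochlear" or "midbrain".
#' @slot nSegments number of Welch segments averaged (0 for midbrain).
#' @export
setClass("ModulationPowerSpectrum",
         representation(power = "matrix", fmAxis = "numeric",
                        omegaAxis = "numeric", omegaUnit = "character",
                        source = "character", nSegments = "numeric"))

setValidity("ModulationPowerSpectrum", function(object) {
  if (nrow(object@power) != length(object@fmAxis) ||
      ncol(object@power) != length(object@omegaAxis))
    return("power dimensions must match axis lengths")
  if (any(object@power < 0)) return("power must be non-negative")
  if (any(object@omegaAxis < 0))
    return("spectral modulation axis must be non-negative")
  if (!object@omegaUnit %in% c("cyc/kHz", "cyc/oct"))
    return("omegaUnit must be 'cyc/kHz' or 'cyc/oct'")
  if (!object@source %in% c("fourier", "cochlear", "midbrain"))
    return("source must be 'fourier', 'cochlear' or 'midbrain'")
  TRUE
})

#' @rdname ModulationPowerSpectrum-class
#' @param x a ModulationPowerSpectrum.
#' @export
setGeneric("mpsPower", function(x) standardGeneric("mpsPower"))
#' @rdname ModulationPowerSpectrum-class
#' @export
setMethod("mpsPower", "ModulationPowerSpectrum", function(x) x@power)

#' @rdname ModulationPowerSpectrum-class
#' @export
setGeneric("fmAxis", function(x) standardGeneric("fmAxis"))
#' @rdname ModulationPowerSpectrum-class
#' @export
setMethod("fmAxis", "ModulationPowerSpectrum", function(x) x@fmAxis)

#' @rdname ModulationPowerSpectrum-class
#' @export
setGeneric("omegaAxis", function(x) standardGeneric("omegaAxis"))
#' @rdname ModulationPowerSpectrum-class
#' @export
setMethod("omegaAxis", "ModulationPowerSpectrum", function(x) x@omegaAxis)

#' @rdname ModulationPowerSpectrum-class
#' @export
setGeneric("omegaUnit", function(x) standardGeneric("omegaUnit"))
#' @rdname ModulationPowerSpectrum-class
#' @export
setMethod("omegaUnit", "ModulationPowerSpectrum", function(x) x@omegaUnit)

#' @rdname ModulationPowerSpectrum-class
#' @export
setGeneric("mpsSource", function(x) standardGeneric("mpsSource"))
#' @rdname ModulationPowerSpectrum-class
#' @export
setMethod("mpsSource", "ModulationPowerSpectrum", function(x) x@source)

setMethod("show", "ModulationPowerSpectrum", function(object) {
  cat(sprintf(
    "ModulationPowerSpectrum (%s): %d fm x %d omega bins\n",
    object@source, nrow(object@power), ncol(object@power)))
  cat(sprintf("  fm in [%.3g, %.3g] Hz; omega in [%.3g, %.3g] %s; %d segments\n",
              min(object@fmAxis), max(object@fmAxis), min(object@omegaAxis),
              max(object@omegaAxis), object@omegaUnit, object@nSegments))
})
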