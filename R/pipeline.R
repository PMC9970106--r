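# End-to-end orchestration: sound ingestion, white-noise calibration of the
# entropy integration ranges, and the per-sound analysis table.

#' Load a sound file as an analysis-ready waveform
#'
#' Reads a WAV file, averages channels to mono, resamples to \code{fs}
#' (44.1 kHz, the rate all decompositions assume) and peak-normalizes.
#'
#' @param path WAV file path.
#' @param fs target sampling rate in Hz.
#' @return A \linkS4class{Waveform}.
#' @export
loadSound <- function(path, fs = 44100) {
  wv <- readWav(path)
  x <- wv$samples
  if (is.matrix(x)) x <- rowMeans(x)
  if (wv$fs != fs) {
    r <- .ratio(fs, wv$fs)
    x <- signal::resample(x, r[1], r[2])
  }
  Waveform(.peak_normalize(x), fs, metadata = list(path = path))
}

.ratio <- function(p, q) {
  g <- .gcd(round(p), round(q))
  c(round(p) / g, round(q) / g)
}

#' White-noise calibration of the modulation entropy ranges
#'
#' Generates seeded white-noise references, runs them through the Fourier
#' and cochlear decompositions, and returns the 90% power-contour extents
#' of their modulation power spectra (averaged over realizations) together
#' with the fixed physiological midbrain caps (500 Hz, 4 cycles/octave).
#' These ranges bound the modulation entropy integration for every
#' representation.
#'
#' @param nRealizations number of white-noise references (default 3).
#' @param noiseDur duration of each in seconds (default 90).
#' @param seeds integer seeds, one per realization.
#' @param gspec a \code{\link{gaborSpec}}.
#' @param cspec a \code{\link{cochlearSpec}}.
#' @param fraction contour power fraction (default 0.9).
#' @param trim edge trim in seconds applied to the representations.
#' @return list of "ModulationRange" objects: \code{fourier},
#'   \code{cochlear}, \code{midbrain}.
#' @export
whiteNoiseRanges <- function(nRealizations = 3, noiseDur = 90,
                             seeds = seq_len(nRealizations),
                             gspec = gaborSpec(30),
                             cspec = cochlearSpec(),
                             fraction = 0.9, trim = 0.05) {
  acc <- list(fourier = c(0, 0), cochlear = c(0, 0))
  units <- list()
  for (s in seeds) {
    w <- whiteNoise(noiseDur, cspec$fs, seed = s)
    for (rep in names(acc)) {
      tf <- if (rep == "fourier") spectrogram(w, gspec, trim = trim)
            else cochleogram(w, cspec, trim = trim)
      ct <- powerContour(welchMps(tf), fraction)
      rm(tf)
      acc[[rep]] <- acc[[rep]] + c(ct$fmMax, ct$omegaMax)
      units[[rep]] <- ct$omegaUnit
    }
  }
  mk <- function(v, unit) structure(
    list(fmMax = v[1], omegaMax = v[2], fraction = fraction,
         threshold = NA_real_, omegaUnit = unit),
    class = "ModulationRange")
  list(fourier = mk(acc$fourier / length(seeds), units$fourier),
       cochlear = mk(acc$cochlear / length(seeds), units$cochlear),
       midbrain = mk(c(500, 4), "cyc/oct"))
}


#' Run the full analysis over a set of sounds
#'
#' For each waveform: Fourier and cochlear power spectra, spectrum slopes
#' and spectral entropies; Fourier, cochlear and midbrain modulation power
#' spectra and modulation entropies. Sounds shorter than one MPS segment
#' are skipped with a warning. Results come back as a tidy table with one
#' row per (sound, representation, metric).
#'
#' @param sounds list of \linkS4class{Waveform}s (e.g. from
#'   \code{\link{buildEnsemble}}), or a character vector of WAV paths.
#' @param ranges entropy integration ranges from
#'   \code{\link{whiteNoiseRanges}}; required for modulation entropies
#'   (NULL computes spectral metrics only).
#' @param gspec a \code{\link{gaborSpec}}.
#' @param cspec a \code{\link{cochlearSpec}}.
#' @param grid an \code{\link{strfGrid}} for the midbrain stage.
#' @param segmentDur Welch segment duration in seconds.
#' @param trim edge trim in seconds.
#' @return data.frame with columns sound, category, representation, metric,
#'   value.
#' @export
runAnalysis <- function(sounds, ranges = NULL, gspec = gaborSpec(30),
                        cspec = cochlearSpec(), grid = strfGrid(),
                        segmentDur = 1.5, trim = 0.05) {
  if (is.character(sounds)) sounds <- lapply(sounds, loadSound)
  if (!length(sounds)) stop("no sounds to analyze")
  rows <- list()
  add <- function(sound, cat, rep, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(
      sound = sound, category = cat, representation = rep, metric = metric,
      value = value, stringsAsFactors = FALSE)
  for (i in seq_along(sounds)) {
    w <- sounds[[i]]
    nm <- w@metadata$path %||% sprintf("sound_%03d", i)
    cat <- w@metadata$category %||% NA_character_
    if (duration(w) < segmentDur + 2 * trim) {
      warning("skipping ", nm, ": shorter than one MPS segment")
      next
    }
    for (rep in c("fourier", "cochlear")) {
      tf <- if (rep == "fourier") spectrogram(w, gspec, trim = trim)
            else cochleogram(w, cspec, trim = trim)
      ps <- powerSpectrum(tf)
      add(nm, cat, rep, "spectral_entropy", spectralEntropy(ps)$entropy)
      add(nm, cat, rep, "spectrum_slope", fitSpectrumSlope(ps)$slope)
      if (!is.null(ranges)) {
        mps <- welchMps(tf, segmentDur)
        me <- modulationEntropy(mps, ranges[[rep]])
        add(nm, cat, rep, "modulation_entropy", me$entropy)
        add(nm, cat, rep, "temporal_modulation_entropy",
            me$temporalMarginal)
        add(nm, cat, rep, "spectral_modulation_entropy",
            me$spectralMarginal)
        if (rep == "cochlear") {
          mm <- midbrainMps(mps, grid)
          mb <- modulationEntropy(mm, ranges$midbrain)
          add(nm, cat, "midbrain", "modulation_entropy", mb$entropy)
          add(nm, cat, "midbrain", "temporal_modulation_entropy",
              mb$temporalMarginal)
          add(nm, cat, "midbrain", "spectral_modulation_entropy",
              mb$spectralMarginal)
        }
      }
      rm(tf)
    }
  }
  if (!length(rows)) stop("no analyzable sounds")
  do.call(rbind, rows)
}

#' Full white-noise calibration of the three representations
#'
#' Runs seeded white-noise references through the complete pipeline and
#' returns the quantities the analysis is calibrated against: spectral
#' entropy under the Fourier and cochlear filterbanks, the 90% power
#' contours of the two modulation power spectra (averaged over
#' realizations), and the modulation entropy of all three representations
#' inside those ranges (midbrain capped at 500 Hz and 4 cycles/octave).
#'
#' @param seeds integer seeds, one white-noise realization each.
#' @param noiseDur duration of each realization in seconds (default 90).
#' @param gspec a \code{\link{gaborSpec}}.
#' @param cspec a \code{\link{cochlearSpec}}.
#' @param grid an \code{\link{strfGrid}}.
#' @param fraction contour power fraction (default 0.9).
#' @param trim edge trim in seconds.
#' @return list with \code{spectralEntropy} (fourier, cochlear),
#'   \code{modulationEntropy} (fourier, cochlear, midbrain),
#'   \code{ranges} (as \code{\link{whiteNoiseRanges}}), and
#'   \code{perSeed}, a data.frame of the per-realization values.
#' @export
whiteNoiseCalibration <- function(seeds = 1:3, noiseDur = 90,
                                  gspec = gaborSpec(30),
                                  cspec = cochlearSpec(),
                                  grid = strfGrid(), fraction = 0.9,
                                  trim = 0.05) {
  mps <- list(fourier = list(), cochlear = list())
  hs <- list(fourier = numeric(0), cochlear = numeric(0))
  ext <- list(fourier = c(0, 0), cochlear = c(0, 0))
  units <- list(fourier = "cyc/kHz", cochlear = "cyc/oct")
  for (s in seq_along(seeds)) {
    w <- whiteNoise(noiseDur, cspec$fs, seed = seeds[s])
    for (rep in c("fourier", "cochlear")) {
      tf <- if (rep == "fourier") spectrogram(w, gspec, trim = trim)
            else cochleogram(w, cspec, trim = trim)
      hs[[rep]] <- c(hs[[rep]], spectralEntropy(powerSpectrum(tf))$entropy)
      m <- welchMps(tf)
      rm(tf); gc(FALSE)
      ct <- powerContour(m, fraction)
      ext[[rep]] <- ext[[rep]] + c(ct$fmMax, ct$omegaMax) / length(seeds)
      mps[[rep]][[s]] <- m
      rm(m); gc(FALSE)
    }
  }
  mkrange <- function(v, unit) structure(
    list(fmMax = v[1], omegaMax = v[2], fraction = fraction,
         threshold = NA_real_, omegaUnit = unit),
    class = "ModulationRange")
  ranges <- list(fourier = mkrange(ext$fourier, "cyc/kHz"),
                 cochlear = mkrange(ext$cochlear, "cyc/oct"),
                 midbrain = mkrange(c(500, 4), "cyc/oct"))
  hm <- list(fourier = numeric(0), cochlear = numeric(0),
             midbrain = numeric(0))
  for (s in seq_along(seeds)) {
    hm$fourier <- c(hm$fourier,
                    modulationEntropy(mps$fourier[[s]],
                                      ranges$fourier)$entropy)
    hm$cochlear <- c(hm$cochlear,
                     modulationEntropy(mps$cochlear[[s]],
                                       ranges$cochlear)$entropy)
    hm$midbrain <- c(hm$midbrain,
                     modulationEntropy(midbrainMps(mps$cochlear[[s]], grid),
                                       ranges$midbrain)$entropy)
  }
  list(spectralEntropy = c(fourier = mean(hs$fourier),
                           cochlear = mean(hs$cochlear)),
       modulationEntropy = c(fourier = mean(hm$fourier),
                             cochlear = mean(hm$cochlear),
                             midbrain = mean(hm$midbrain)),
       ranges = ranges,
       perSeed = data.frame(seed = seeds,
                            spectral_fourier = hs$fourier,
                            spectral_cochlear = hs$cochlear,
                            modulation_fourier = hm$fourier,
                            modulation_cochlear = hm$cochlear,
                            modulation_midbrain = hm$midbrain))
}
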