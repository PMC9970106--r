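Package: audmod
Title: Physiologically Inspired Auditory Decompositions and Modulation
    Statistics of Natural Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage auditory analysis of sound waveforms: an ERB-scaled
    gammatone cochlear filterbank with Hilbert envelopes and a synaptic
    lowpass (cochleogram), a constant-Q spectro-temporal receptive field
    (STRF) midbrain filterbank, and constant-resolution Gabor (short-term
    Fourier) spectrograms as the reference decomposition. Provides
    Welch-averaged modulation power spectrum estimators, normalized spectral
    and modulation entropy metrics, spectrum slope fitting, the
    bandwidth-scaling gain predictions of output whitening, the Greenwood
    cochlear map hair-cell gain, and seeded synthetic-sound generators
    (white noise, power-law spectra with 1/f^a envelope modulations, and
    harmonic vocalization surrogates) that emulate natural sound ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
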