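---
title: "Auditory filterbank decompositions and the whitening of natural sound statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory filterbank decompositions and the whitening of natural sound statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`audmod` implements a two-stage, physiologically inspired decomposition of
sound and the statistics used to ask whether those stages *whiten* natural
sounds, i.e. equalize power across the neural channels that carry them.

**Cochlear stage.** A waveform $s(t)$ is passed through $N = 664$
gammatone filters with impulse responses

$$h_k(t) = A\, t^{n-1} \cos(2\pi f_k t)\, e^{-2\pi b(f_k) t}\, u(t),$$

with characteristic frequencies $f_k = 100 \cdot 2^{0.01k}$ Hz
($k = 1,\dots,664$, spanning 100 Hz-10 kHz at 0.01-octave steps) and
equivalent rectangular bandwidths $b(f) = 24.7\,(4.37 f/1000 + 1)$ Hz, so
bandwidth grows roughly proportional to CF. Each channel's Hilbert
envelope is lowpass filtered by a synaptic kernel (a cubic B-spline scaled
to a 750 Hz cutoff, modeling the loss of synchronization at the hair-cell
synapse) and resampled to 2 kHz, giving the cochleogram
$S_C(t, x_k)$ on an octave axis $x_k = \log_2(f_k/100)$.

**Midbrain stage.** The cochleogram is analyzed by a bank of Gabor-alpha
spectro-temporal receptive fields

$$\mathrm{STRF}(t,x) = A_m \frac{t}{\tau} e^{-(t-\tau)/\tau}
  e^{-2x^2/bw^2} \cos(2\pi\Omega_0 x + 2\pi f_{m0} t + \phi)\, u(t)$$

tuned to best temporal modulations $f_{m0} = \pm 2\dots512$ Hz
(quarter-octave steps) and best spectral modulations
$\Omega_0 = 0.1\dots3.6$ cyc/oct (tenth-octave steps). The decay
$\tau = \sqrt{\sqrt{2}-1}/(\pi |f_{m0}|)$ and spread
$bw = 2\sqrt{2\ln 2}/(\pi \Omega_0)$ tie the modulation bandwidths to the
best frequencies (quality factor $\approx 1$), so the bank tiles the
modulation plane like a 2-D wavelet transform: filter bandwidth, and hence
integrated power on featureless inputs, grows as $|f_{m0}|\cdot\Omega_0$.

**Fourier reference.** Constant-resolution Gabor spectrograms (Gaussian
windows with two-sigma bandwidths $\Delta f$ = 30, 120 or 480 Hz, sitting
exactly on the uncertainty bound $\Delta t\,\Delta f = 1/\pi$) provide the
non-physiological baseline against which whitening is measured.

**Statistics.** For each representation the package computes the
per-channel power spectrum, its normalized Shannon (spectral) entropy
$H_S = H / \log_2 N$, the Welch-averaged modulation power spectrum (MPS),
the normalized modulation entropy $H_M$ over a bounded modulation range,
linear spectrum-slope fits on the representation's native axis (dB/kHz or
dB/octave), and the mechanistic gain predictions: the ERB bandwidth gain
$10\log_{10} b(f)$ that predicts cochlear whitening of declining spectra,
the modulation-bandwidth gain $10\log_{10}(|f_{m0}|\,\Omega_0)$ that
predicts midbrain whitening of $1/f$-like modulation spectra, and the
Greenwood-map hair-cell density gain (about +8 dB for the top octave of
hearing over the bottom one).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| CF grid | $100\cdot2^{0.01k}$, $k=1..664$ | Hz | the $k=0$ convention would give 665 channels; the grid is defined to start one step above 100 Hz |
| gammatone order $n$ | 4 | - | standard auditory-nerve fit; exposed in `cochlearSpec()` |
| synaptic cutoff | 750 | Hz | limits envelope synchronization; cubic B-spline kernel, -3 dB at the cutoff |
| envelope rate | 2000 | Hz | Nyquist 1 kHz covers the 750 Hz cutoff and the 512 Hz top STRF rate |
| Gabor $\Delta f$ | 30 (also 120, 480) | Hz | the three analysis resolutions; $\sigma = 1/(\sqrt2 \pi \Delta f)$ |
| Gabor channel spacing | 10 | Hz | spectral-modulation Nyquist 50 cyc/kHz, far above the white-noise contour; spacing cancels in normalized entropy |
| Welch segment | 1.5 | s | modulation resolution ~0.8 Hz; 2-D Kaiser window, $\beta = 3.4$ |
| STRF grid edges | 2-512 Hz, 0.1-3.6 cyc/oct | - | lower temporal edge is a package choice (physiological grids are stated by their upper edge); entropies are normalized by bin counts so moderate edge changes are second-order |
| STRF phase $\phi$ | 0 | rad | outputs used here depend on $|\mathrm{MTF}|$, which is weakly phase-dependent; exposed in `strfKernel()` |
| entropy ranges | white-noise 90% contour; midbrain capped at 500 Hz, 4 cyc/oct | - | modulations that the decomposition can reliably represent |

## Numerical and design choices

**Gammatone filtering.** The filterbank runs as an analytic (complex)
gammatone: a cascade of $n$ identical complex one-pole recursions whose
output magnitude *is* the Hilbert envelope of the real filter output.
This is exactly the impulse-invariant discretization of the analytic part
of $h_k(t)$, it is normalized numerically to unit peak gain (the cascade
peak is $(1-r)^{-n}$ at the CF), and it costs $O(nN)$ per channel, which
is what makes 90-second calibration runs with 664 channels routine. The
residual difference from real-filter-plus-Hilbert is the negative-frequency
leakage of the complex filter, below $10^{-3}$ relative even for the
lowest CF. Envelopes are clipped at zero after the synaptic lowpass (the
B-spline kernel is non-negative, so this is a formality), and statistics
functions discard 50 ms at each edge to drop filter transients.

**Gabor spectrograms** are computed exactly in the frequency domain: one
FFT of the waveform, per-channel weighting by the Gaussian transfer
function (truncated at $6\sigma_f$, amplitude $10^{-4}$), and
reconstruction of the analytic channel signal directly on the 2 kHz frame
grid. This is equivalent to time-domain Gabor filtering without window
truncation artifacts.

**MPS estimation and the DC convention.** Envelope representations have a
large mean (for Gaussian noise, about 79% of envelope power is its DC),
and the time-averaged spectral profile of the cochleogram is itself a
smooth function of channel. Left in place, this mass concentrates at and
around $f_m = 0$ and dominates both the power contour and the entropy
normalization. The spectral profile is the domain of the *spectral*
entropy, so by default `welchMps()` removes each channel's window-weighted
temporal mean per segment (`demean = "channel"`); the MPS then describes
temporal modulations proper. This convention reproduces the white-noise
calibration the analysis is anchored to (cochleogram contour reaching
about 500 Hz; all three representations with modulation entropy near
0.93-0.96); retaining the DC collapses the cochleogram's modulation
entropy to about 0.70 by loading a handful of $f_m \approx 0$ bins.
`demean = "global"` and `"none"` are available for inspection. The channel
dimension of the segment FFT is zero-padded to a smooth composite length,
which interpolates the spectral-modulation axis onto round values (0.1
cyc/kHz for the 991-channel Fourier bank) and keeps prime-length
transforms out of the hot path.

**Midbrain MPS routes.** The default route weights the cochleogram MPS by
the squared closed-form modulation transfer functions and integrates
(Parseval route); it is separable in the two axes and runs in milliseconds
for the whole 3432-filter grid. The time-domain route convolves sampled
STRF kernels with the cochleogram; it averages output power over the
temporally settled region and over channels whose spectral kernel fits
inside the represented octave range. The two agree within a few percent
per filter on stationary inputs for filters that the 6.64-octave cochlea
can actually realize. Filters with $\Omega_0 \lesssim 0.5$ cyc/oct have
Gaussian spreads wider than the hearing range itself; their time-domain
outputs are necessarily edge-truncated, and the modulation-domain route
(which represents the ideal filter) is the defined behavior.

**Bandwidth conventions for Q = 1.** The secondary-parameter design
formulas imply slightly different width conventions on the two axes: with
$\tau = \sqrt{\sqrt2 - 1}/(\pi|f_{m0}|)$ the temporal $|\mathrm{MTF}|$
reaches width $|f_{m0}|$ at its half-power point, while with
$bw = 2\sqrt{2\ln2}/(\pi\Omega_0)$ the spectral profile reaches width
$\Omega_0$ at its half-amplitude point. The package keeps these
constants and measures each axis at its design convention; both normalized
bandwidths are then 1 within 5% across the grid.

**Entropy normalization.** The raw entropy is computed on the unit-sum
power distribution and divided by $\log_2$ of the retained bin count, so
$H_S, H_M \in [0, 1]$ by construction and both are invariant to global
power scaling. Slope standardization uses the sample (n-1) standard
deviation.

**Prediction alignment.** Spectrum predictions are defined up to an
additive dB constant (absolute gain is arbitrary), so predictions are
aligned to measurements by a least-squares offset before reporting the
mean absolute error; the reported error is invariant to global dB shifts
of either input. Interpolation of dB spectra is linear in log frequency
(and bilinear in log-log modulation coordinates for the midbrain
prediction).

## The synthetic-sound generators

No natural-recording corpus ships with the package; seeded generators
emulate the statistical structure the analysis assumes:

- `whiteNoise()`: the flat-spectrum reference every range calibration
  uses.
- `powerLawSound()`: frequency-domain synthesis (shaped magnitude, random
  phase, inverse transform over a 50 Hz-11 kHz band) with an exact
  dB/kHz spectral slope, multiplied by a positive envelope whose
  modulation power follows $f_m^{-\alpha}$ over 0.3-200 Hz. Natural
  ensembles are emulated with gentle slopes (about -0.5 to -3 dB/kHz) and
  $\alpha \approx 1$, matching the declining spectra and $1/f$-like
  modulation statistics of natural recordings: the ERB gain (~15 dB
  across the hearing range, equivalent to ~1.5 dB/kHz) then brackets the
  ensemble, so cochlear slopes straddle zero as natural corpora do.
- `harmonicVocalization()`: harmonic stacks (f0 near 100-170 Hz) with
  formant-shaped envelopes and slow amplitude modulation, the surrogate
  for voiced vocalizations.

What these generators do *not* emulate: temporal sparseness and
intermittency, harmonicity-modulation correlations, category-specific
modulation shapes, or any particular recording. Tests passing on these
surrogates therefore validate the *mechanisms* (bandwidth-scaling gains,
entropy orderings) under the stated first-order statistics, not
corpus-level values, which depend on the actual media; per-category
statistics of real recording collections are out of scope for the same
reason.

When measuring the realized modulation exponent, the wideband
($\Delta f = 480$) spectrogram is the right instrument: its intrinsic
envelope-fluctuation spectrum is spread over ~±300 Hz, an order of
magnitude lower in density than the narrowband bank's, so the imposed
$1/f^\alpha$ trend dominates the marginal over the 1-16 Hz fit range.

## Problem sizes used by the tests

The acceptance-level checks run the calibration the analysis prescribes:
three seeded 90 s white-noise realizations through the full pipeline
(about five minutes of CPU). Property suites use shorter seeded inputs
(8-60 s) and synthetic envelope fields built directly in code, chosen so
each property is measured well inside its tolerance while the whole suite
stays desk-scale.

## Known limitations

- The cochlear model is linear: no compression, suppression, adaptation
  or spiking; hair-cell density gain is reported as a separate analytic
  curve (`hairCellGainDb()`), not built into the filterbank.
- Time-domain STRF filtering of the lowest spectral-modulation filters is
  edge-limited by the finite octave range (see above).
- The Welch estimator inherits Kaiser ($\beta = 3.4$) sidelobes around
  -27 dB; where the true modulation spectrum has decayed further, leakage
  sets the floor. This is visible as a few-percent disagreement between
  the two midbrain routes at high $\Omega_0$ on steep-spectrum inputs.
- Printed second-moment resolution values for individual cochlear filters
  (e.g. the 45 ms integration time sometimes quoted for a 100 Hz filter)
  are convention-dependent; the package asserts the uncertainty-bound and
  monotonicity properties, which are convention-free, and documents its
  moment convention (energy densities of envelope and transfer magnitude).
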