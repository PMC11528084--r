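---
title: "Derived-band analysis of the parallel ABR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derived-band analysis of the parallel ABR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pabr)
```

## The problem

The auditory brainstem response (ABR) to a frequency-specific toneburst does
not necessarily come from the cochlear place tuned to that frequency: at
clinically useful levels, excitation spreads along the cochlea, especially
toward high-characteristic-frequency (basal) regions. The parallel ABR
(pABR) paradigm presents independently Poisson-timed toneburst trains at
five octave-spaced frequencies simultaneously and separates the responses by
cross-correlation; because the trains are mutually uncorrelated, each train
may also act as a masker for the others, potentially *improving* place
specificity relative to presenting one frequency at a time.

`pabr` implements the full measurement chain used to test that idea with
high-pass-noise (HPN) derived bands: stimulus construction, a parametric
forward simulation of the EEG, response extraction, derived-band
subtraction, and a noise-corrected response-size statistic, plus an
orchestrator that exports tidy tables ready for external mixed-model fits.

## Stimuli

Tonebursts are windowed sinusoids of `n_cycles / frequency` duration
(default five Blackman-windowed cycles — the toneburst envelope is
configurable because published pABR work varies in this detail). Timing
comes from homogeneous Poisson processes at 20, 40 or 100 stimuli/s,
quantized to the 48 kHz audio grid. Exactly half of the impulses are
polarity-flipped (for odd counts the extra impulse's sign is randomized so
the expected surplus is zero); rarefaction and condensation responses then
average together while electrical stimulus artifact cancels. Serial stimuli
are the identical ensemble with a single train presented in isolation.

Maskers are pink noise, high-pass filtered in half-octave cutoff steps:
250–16000 Hz for parallel conditions (13 cutoffs) and one octave below to
two octaves above the test frequency for serial conditions (7 cutoffs). The
noise is synthesized spectrally and shaped by the squared magnitude of an
8th-order Butterworth high-pass response — the zero-phase equivalent of a
forward-backward pass, chosen because an 8th-order transfer-function
recursion at a 250 Hz cutoff on a 48 kHz grid is numerically fragile while
the spectral product is exact and stable. Attenuation one octave below the
cutoff exceeds 90 dB, comfortably past the 60 dB the derived-band logic
requires.

Levels use a documented digital convention, not physical calibration: a
full-scale sinusoid is defined as 110 dB SPL. Toneburst levels in dB peSPL
scale the waveform peak to a reference sinusoid's peak (default 75 dB
peSPL); noise levels scale RMS (69 or 72 dB SPL).

## The forward model

The paper-level analysis needs EEG whose band structure is known, so the
simulator is a phenomenological cochlear-place model, not auditory
biophysics. Each (stimulus frequency `f`, band `b`) pair has an excitation
weight

\[ A[f, b] = \exp\left(-\tfrac{1}{2} (d / w(d))^2\right), \qquad
   d = \log_2(\mathrm{CF}_b / f), \]

with apical width `w = 0.5` octaves for `d < 0` and basal width
`0.5 * (1 + basal_skew)` (default skew 1.5, so 1.25 octaves) for `d > 0` —
the asymmetric basal spread seen at high stimulus levels. Band latencies
follow `5 + 7 (CF/250)^{-0.4}` ms, strictly decreasing in CF (about 12 ms at
250 Hz down to 6.3 ms at 16 kHz); only the monotonicity matters for the
place-specificity read-outs. Each band contributes a Gaussian-windowed
single-cycle cosine kernel (4 ms wide) at its latency, scaled so the
on-frequency response peaks at 150 nV at 20 stimuli/s.

Three multiplicative effects modify the gains:

* **Masking.** Bands with CF at or above the HPN cutoff are multiplied by
  the masking residual ε (default 0, perfect masking; positive values
  emulate incomplete masking).
* **Adaptation.** All gains scale as `(rate/20)^{-0.3}`; responses shrink
  at higher rates.
* **Parallel suppression.** Under parallel presentation, off-frequency
  excitation is multiplied by `1 - p(rate) * min(1, |d|)` with
  `p(rate) = 0.3 (rate/20)`, capped at 0.95. The linear rate growth is
  deliberate: it outpaces the adaptation exponent, so the serial-minus-
  parallel difference in off-frequency response size *widens* with rate —
  the hypothesis the analysis is designed to detect. These numbers are the
  simulator's own; the source experiments report no quantitative forward
  model.

Noise is pink (or white) with a per-trial standard-deviation multiplier
`exp(0.5 z_t)`, where `z_t` follows a stationary AR(1) with lag-one
correlation 0.9 across consecutive one-second trials. The heterogeneity
makes inverse-variance weighting consequential; the serial correlation
reflects how EEG noise actually behaves (movement, muscle tone and
vigilance drift over many seconds) and keeps the prestimulus noise floor
representative: the averaged waveform's prestimulus lags sample the
*neighboring* trials under surround padding, so independent per-second
variances would make the noise floor systematically unrepresentative of the
in-window noise and bias the response-size statistic negative.

## Response calculation

Raw EEG (10 kHz) is bandpass filtered 30–2000 Hz with a causal first-order
Butterworth filter and notch filtered at odd multiples of 60 Hz up to
2500 Hz (21 causal biquads, 5 Hz bandwidth). Filtering is causal on
purpose: latencies shift identically across conditions, so comparisons
survive.

For each trial, the impulse train is rectified (all magnitudes 1),
downsampled to the EEG rate by index rounding (collisions merge to a single
unit impulse, with a warning), zero-padded by 1 s on each side, and
cross-correlated with the correspondingly extended EEG in the frequency
domain:

\[ w = \frac{1}{n} \mathcal{F}^{-1}\{ \mathcal{F}\{x\}^* \mathcal{F}\{y\} \}. \]

Padding the EEG with the *surrounding recording* (zeros past the session
edges) removes circular artifacts; the result equals the brute-force epoch
average to machine precision. Trials are combined with Bayesian weights —
the inverse of each trial's raw-EEG variance, normalized to sum to one. The
stored lag window is −500 to +600 ms: wide enough for the 40 prestimulus
noise windows below while keeping a margin at lag 0.

## Derived bands and response size

Responses whose HPN cutoffs are one octave apart are subtracted
(`response(2c) − response(c)`), isolating the octave of cochlea between the
cutoffs; the band is labeled by the geometric mean of the cutoffs (707 and
1414 Hz give the 1000 Hz band). Summing the non-overlapping pairs
telescopes exactly to `response(16 kHz) − response(250 Hz)`.

Because derived responses have poor SNR, response size is the
noise-corrected standard deviation

\[ \sigma_R = \mathrm{sign}(v)\sqrt{|v|}, \qquad
   v = \sigma^2_{R+N} - \sigma^2_N, \]

where `σ²_{R+N}` is the waveform variance in a 12 ms window centered at the
expected latency (the mean of the two parent responses' wave V latencies)
and `σ²_N` is the mean variance of 40 non-overlapping 12 ms windows covering
lags −492 to −12 ms (the 12 ms gap before 0 avoids filter edge effects).
The signed square root keeps bias-corrected negative estimates
representable, which plots and models need.

## Automated wave V picking

Peak picking was manual in the source experiments; here it is an algorithm,
and that is a deliberate deviation. The waveform is smoothed with a
zero-phase 0.5 ms Gaussian (wave V is a millisecond-scale feature; smoothing
suppresses narrow noise extrema without moving broad peaks), then the
largest positive local maximum in the physiologic window (default 4–20 ms)
that is followed by a trough within 6 ms is taken, provided its prominence
(peak minus trough) exceeds 6 smoothed-prestimulus standard deviations.
The threshold was set from the noise side: the maximum prominence of pure
noise in a 16 ms window is about 5 prestimulus SDs at its 99th percentile,
so 6 keeps false picks under 5%, while genuine responses at usable SNR
exceed 15–20 SDs. A response below threshold returns `NA` and the condition
is excluded from latency analyses; where a window center is still needed for
the size statistic, the pipeline falls back to the largest in-window peak
regardless of prominence (the single-run analog of using grand-average
latencies).

## Problem sizes and paired designs

The package's own validation runs use scaled-down sessions chosen for
statistical adequacy: 5 minutes per condition for latency sweeps, 10 minutes
per condition (the standard session allotment) for serial-versus-parallel
size comparisons, and 200-seed Monte-Carlo runs for the estimator checks.
Qualitative comparisons across paradigms and cutoffs share stimulus trains
and noise streams (common random numbers): exactly as in a repeated-measures
experiment, the paired design removes between-run noise variance from the
contrast of interest. The derived-band subtraction then cancels shared noise
along with shared off-band response, which is what makes desk-scale
reproductions of the direction of the group-level findings feasible.

## What the simulation does and does not show

Passing tests demonstrate that the analysis chain — extraction, weighting,
derivation, size estimation, peak picking — recovers the structure the
forward model embeds, at realistic SNR, and that the paradigm-level
contrasts emerge in the programmed direction. They do not validate the
forward model against human EEG: real wave V morphology varies across
subjects, masking is demonstrably incomplete in real recordings (ε > 0),
electrode noise is not exactly pink, and octopus-cell pathways may compress
the latency-by-CF map the simulator assumes. Group-level statistics from
the source experiments (F tables, group latencies and sizes) derive from
12-subject human data and are out of scope; the pipeline instead exports
per-run tidy tables an external `lme4`-style fit would consume.

## Numerical choices

* Poisson trains are unconstrained (no dead time); overlapping tonebursts
  sum.
* Downsampling collisions keep one unit impulse, preserving the unit-
  magnitude convention, and are logged.
* Extraction padding is 1 s per side, more than the longest stored lag.
* The toneburst grid and band labels snap to nominal half-octave values
  (354, 707, 1414, ... Hz); octave checks use a 2% log tolerance so nominal
  rounding never breaks pairing.
* All randomness flows from one master seed through deterministic child
  seeds (kept below 2^31), so every artifact of a run is reproducible.

## A worked example

```{r example, eval = FALSE}
library(pabr)

cfg <- pabr_config(paradigms = "serial", test_frequencies_hz = 500,
                   rates_per_s = 40, minutes_per_condition = 5)
res <- run_pabr_pipeline(cfg, out_dir = tempfile("pabr"), seed = 1)
dplyr::filter(res, kind == "derived")
plot_response_sizes(res)
```

The masked rows of `res` hold wave V latencies per HPN cutoff; the derived
rows hold `sigma_r_v` per band — one row per condition, the shape an
external mixed-effects analysis consumes.
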