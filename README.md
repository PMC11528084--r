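# pabr

Stimulus generation, EEG simulation and derived-band analysis for the
**parallel auditory brainstem response (pABR)** paradigm.

## The problem

Frequency-specific auditory brainstem responses (ABRs) are the standard
objective test of hearing across frequency, but a toneburst at one frequency
can recruit cochlear regions far from its place — especially basal (high
characteristic frequency) regions at clinical stimulus levels — so the
measured response is not necessarily *place specific*. The pABR paradigm
presents independently Poisson-timed toneburst trains at five octave-spaced
frequencies (500–8000 Hz) at once and separates the responses by
cross-correlation; because the trains are mutually uncorrelated, each train
can also mask the others, which may improve place specificity while speeding
the exam.

`pabr` implements the measurement chain used to quantify that effect with
high-pass-noise (HPN) **derived bands**, for researchers in auditory
electrophysiology and anyone building evoked-response tooling:

* **Stimuli** — windowed tonebursts, Poisson impulse trains with exact-half
  polarity splits, parallel/serial assembly, and high-pass pink-noise
  maskers on the half-octave cutoff grid (13 parallel conditions, 7 serial).
* **Synthetic EEG** — a parametric cochlear-place forward model (asymmetric
  basal spread, decreasing latency with CF, rate adaptation, parallel
  suppression, optional incomplete masking) plus heteroscedastic noise, so
  every downstream stage is testable with known ground truth.
* **Response extraction** — causal 30–2000 Hz bandpass and 60 Hz-odd-harmonic
  notches, impulse-train downsampling, padded frequency-domain
  cross-correlation

  `w = (1/n) F⁻¹{ F{x}* F{y} }`

  (equal to epoch averaging, without circular artifacts), and Bayesian
  (inverse-variance) trial weighting.
* **Derived bands** — octave-apart subtraction with geometric-mean band
  labels, automated wave V latency picking, and the noise-corrected response
  size

  `σ_R = sign(v)·√|v|,  v = σ²(R+N) − σ²(N)`

  with the noise floor taken from 40 non-overlapping 12 ms prestimulus
  windows.
* **Pipeline** — `run_pabr_pipeline()` runs stimulus → simulate → extract →
  derive → report end to end, deterministically from one seed, and writes a
  tidy CSV (one row per condition and band) ready for an external
  mixed-effects fit.

All levels follow a documented digital convention (full-scale sinusoid =
110 dB SPL); no physical calibration is implied.

## A worked example

Simulate a serial 500 Hz session at 40 stimuli/s (5 min per masker
condition), extract responses at every HPN cutoff, and summarize:

```r
library(pabr)

cfg <- pabr_config(paradigms = "serial", test_frequencies_hz = 500,
                   rates_per_s = 40, minutes_per_condition = 5)
res <- run_pabr_pipeline(cfg, out_dir = "pabr-demo", seed = 1)
print(dplyr::select(dplyr::filter(res, kind == "masked"),
                    cutoff_hz, latency_ms), n = 7)
#> # A tibble: 7 × 2
#>   cutoff_hz latency_ms
#>       <dbl>      <dbl>
#> 1       250       NA
#> 2       354       NA
#> 3       500       NA
#> 4       707       10.5
#> 5      1000       10.1
#> 6      1414        9.7
#> 7      2000        9.8
print(dplyr::select(dplyr::filter(res, kind == "derived"),
                    band_center_hz, sigma_r_v))
#> # A tibble: 5 × 2
#>   band_center_hz sigma_r_v
#>            <dbl>     <dbl>
#> 1            354  -8.43e-9
#> 2            500   4.33e-8
#> 3            707   4.46e-8
#> 4           1000   5.03e-8
#> 5           1414   3.50e-8
```

Reading the output: at low cutoffs the masker covers the whole response
region, so no wave V clears the detection threshold (`NA`); as the cutoff
rises past the stimulus frequency, latency falls as earlier, more basal
bands unmask (10.5 → 9.7 ms here). The derived rows give the noise-corrected
response size per octave band in volts — the profile peaks around the
500–1000 Hz bands (43–50 nV) and falls off on both sides, with the fully
masked 354 Hz band at the noise floor (slightly negative values are expected
from the bias correction). `plot_latencies(res)` and
`plot_response_sizes(res)` draw the standard summary figures.

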