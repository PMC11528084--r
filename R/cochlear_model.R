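#' Parametric cochlear-place forward model
#'
#' Describes how much each half-octave cochlear band contributes to the
#' scalp-recorded wave-V-like response for each toneburst frequency, and how
#' those contributions change with masking, stimulus rate and parallel
#' presentation. The model is phenomenological: it encodes only the
#' statistical structure the derived-band analysis assumes (asymmetric basal
#' spread of excitation at high levels, shorter latencies at more basal
#' places, rate-dependent adaptation, cross-stimulus masking under parallel
#' presentation, and optionally incomplete high-pass-noise masking), not
#' auditory-periphery biophysics.
#'
#' Excitation of band `b` (center frequency CF) by a toneburst at `f` is a
#' Gaussian in octave distance `d = log2(CF/f)` with width
#' `spread_apical_oct` on the apical side (`d < 0`) and
#' `spread_apical_oct * (1 + basal_skew)` on the basal side, so excitation
#' spreads preferentially toward high CFs.
#'
#' @param stim_frequencies_hz toneburst frequencies (default the standard
#'   five octave-spaced frequencies 500–8000 Hz)
#' @param band_centers_hz cochlear band centers (default the half-octave
#'   grid 250–16000 Hz)
#' @param response_peak_v peak scalp amplitude, in volts, of the
#'   on-frequency band response at 20 stimuli/s (default 150 nV)
#' @param spread_apical_oct Gaussian width (octaves) of apical excitation
#'   spread (default 0.5)
#' @param basal_skew nonnegative asymmetry factor; the basal width is
#'   `spread_apical_oct * (1 + basal_skew)` (default 1.5)
#' @param adaptation_exponent amplitude scales as `(rate/20)^-exponent`
#'   (default 0.3)
#' @param parallel_suppression base suppression of off-frequency excitation
#'   under parallel presentation at 20 stimuli/s, in `[0, 1]` (default 0.3)
#' @param suppression_rate_exponent suppression grows as
#'   `(rate/20)^exponent` (default 1), capped at 0.95
#' @param masking_residual epsilon in `[0, 1]`: fraction of excitation that
#'   survives above the high-pass-noise cutoff; 0 is perfect masking,
#'   positive values emulate incomplete masking
#' @param latency_fun function mapping band CF (Hz) to wave V latency (ms);
#'   must be strictly decreasing in CF. Default
#'   `5 + 7 * (CF/250)^-0.4` ms.
#' @return an object of class `cochlear_band_model` containing the
#'   excitation matrix `A` (stimulus frequency by band) and per-band
#'   latencies
#' @export
cochlear_band_model <- function(stim_frequencies_hz = c(500, 1000, 2000, 4000, 8000),
                                band_centers_hz = half_octave_grid(250, 16000),
                                response_peak_v = 150e-9,
                                spread_apical_oct = 0.5,
                                basal_skew = 1.5,
                                adaptation_exponent = 0.3,
                                parallel_suppression = 0.3,
                                suppression_rate_exponent = 1,
                                masking_residual = 0,
                                latency_fun = function(cf) 5 + 7 * (cf / 250)^-0.4) {
  stopifnot(basal_skew >= 0, spread_apical_oct > 0,
            parallel_suppression >= 0, parallel_suppression <= 1,
            masking_residual >= 0, masking_residual <= 1,
            response_peak_v >= 0)
  bands <- as.numeric(band_centers_hz)
  lat <- latency_fun(bands)
  if (any(diff(lat) >= 0))
    abort("latency_fun must be strictly decreasing in band CF")
  A <- matrix(0, length(stim_frequencies_hz), length(bands),
              dimnames = list(as.character(stim_frequencies_hz),
                              as.character(band_centers_hz)))
  for (i in seq_along(stim_frequencies_hz)) {
    d <- log2(bands / stim_frequencies_hz[i])
    width <- ifelse(d < 0, spread_apical_oct,
                    spread_apical_oct * (1 + basal_skew))
    A[i, ] <- exp(-0.5 * (d / width)^2)
  }
  structure(
    list(stim_frequencies_hz = as.numeric(stim_frequencies_hz),
         band_centers_hz = bands, A = A, latency_ms = lat,
         response_peak_v = response_peak_v,
         spread_apical_oct = spread_apical_oct, basal_skew = basal_skew,
         adaptation_exponent = adaptation_exponent,
         parallel_suppression = parallel_suppression,
         suppression_rate_exponent = suppression_rate_exponent,
         masking_residual = masking_residual),
    class = "cochlear_band_model"
  )
}

#' EEG noise model for the forward simulator
#'
#' Additive background noise with per-trial variance heterogeneity: each
#' one-second trial's noise standard deviation is `base_std_v` times a
#' log-normal factor, which makes inverse-variance (Bayesian) trial weighting
#' consequential. An optional mains component at `line_hz` can be added.
#'
#' @param spectrum `"pink"` or `"white"`
#' @param base_std_v baseline per-sample noise standard deviation in volts
#'   (default 5 microvolts, typical of a quiet raw EEG channel)
#' @param trial_sd_log log-normal sigma of the per-trial std multiplier
#'   (default 0.5)
#' @param trial_ar lag-one autocorrelation of the per-trial log-std across
#'   consecutive trials (default 0.9). EEG noise level drifts slowly —
#'   movement, muscle tone and vigilance persist over many seconds — so
#'   neighboring one-second trials have similar noise variance; independent
#'   per-second variances would be unphysical and would also make the
#'   prestimulus noise floor unrepresentative of the in-window noise (the
#'   inverse-variance weights are matched to each trial, but prestimulus
#'   lags of the averaged response sample the neighboring trials)
#' @param line_hz mains frequency, or `NULL` for none
#' @param line_amplitude_v mains sinusoid amplitude in volts
#' @return an object of class `noise_model`
#' @export
noise_model <- function(spectrum = c("pink", "white"), base_std_v = 5e-6,
                        trial_sd_log = 0.5, trial_ar = 0.9, line_hz = NULL,
                        line_amplitude_v = 0) {
  spectrum <- match.arg(spectrum)
  stopifnot(base_std_v >= 0, trial_sd_log >= 0, trial_ar >= 0, trial_ar < 1)
  structure(
    list(spectrum = spectrum, base_std_v = base_std_v,
         trial_sd_log = trial_sd_log, trial_ar = trial_ar, line_hz = line_hz,
         line_amplitude_v = line_amplitude_v),
    class = "noise_model"
  )
}

#' Wave-V-like response kernel
#'
#' A smooth biphasic surrogate for the wave V complex: a single cosine cycle
#' under a Gaussian envelope, peaking at the requested latency with the
#' requested peak amplitude. The kernel starts at lag 0 (toneburst onset) so
#' that placing it at each impulse index yields a response peaking
#' `latency_ms` after the toneburst.
#'
#' @param latency_ms peak latency in ms (must be nonnegative)
#' @param amplitude peak amplitude (volts)
#' @param fs_hz sampling rate in Hz
#' @param width_ms cosine period and effective kernel width in ms (default
#'   4); the Gaussian envelope sigma is `width_ms / 4`
#' @return numeric kernel sampled from lag 0 to `latency_ms + 2 * width_ms`
#' @export
wave_v_kernel <- function(latency_ms, amplitude, fs_hz = 10000, width_ms = 4) {
  stopifnot(latency_ms >= 0, width_ms > 0)
  n <- round((latency_ms + 2 * width_ms) / 1000 * fs_hz) + 1
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  u <- t_ms - latency_ms
  amplitude * exp(-0.5 * (u / (width_ms / 4))^2) * cos(2 * pi * u / width_ms)
}
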