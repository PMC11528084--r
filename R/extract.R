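#' Averaged evoked-response waveform container
#'
#' @param w voltage series over the stored lag window
#' @param fs_hz sampling rate
#' @param lag_window_s two-element lag window in seconds relative to
#'   toneburst onset (default -0.5 to 0.6)
#' @param n_stimuli total number of stimuli averaged (n)
#' @param n_trials number of trials contributing
#' @param condition condition metadata list
#' @param weights optional per-trial weights used in the average
#' @return an object of class `response_waveform`
#' @export
response_waveform <- function(w, fs_hz, lag_window_s = c(-0.5, 0.6),
                              n_stimuli = NA_integer_, n_trials = NA_integer_,
                              condition = list(), weights = NULL) {
  stopifnot(all(is.finite(w)))
  lag_lo <- round(lag_window_s[1] * fs_hz)
  lag_hi <- round(lag_window_s[2] * fs_hz)
  stopifnot(length(w) == lag_hi - lag_lo + 1)
  structure(
    list(w = as.numeric(w), fs_hz = fs_hz, lag_window_s = lag_window_s,
         lag_ms = seq(lag_lo, lag_hi) / fs_hz * 1000,
         n_stimuli = n_stimuli, n_trials = n_trials,
         condition = condition, weights = weights),
    class = "response_waveform"
  )
}

#' @export
print.response_waveform <- function(x, ...) {
  cat(sprintf("<response_waveform> lags %g..%g ms @ %g Hz, n = %s stimuli\n",
              min(x$lag_ms), max(x$lag_ms), x$fs_hz, x$n_stimuli))
  invisible(x)
}

#' Cross-correlate one trial's impulse train with its EEG
#'
#' Core of the response calculation: the rectified unit-magnitude impulse
#' train `x` is zero-padded on both sides, the EEG `y` is padded with the
#' *surrounding* recording (zeros past the session edges), and
#' `w = (1/n) * IFFT(conj(FFT(x)) * FFT(y))` is evaluated, which equals the
#' epoch average over the stored lag window while remaining efficient and
#' free of circular artifacts.
#'
#' @noRd
xcorr_trial <- function(samples, start1, L, idx0_local, n_imp, pad,
                        lag_lo, lag_hi) {
  N <- L + 2L * pad
  x <- numeric(N)
  x[pad + idx0_local + 1L] <- 1
  lo <- start1 - pad
  hi <- start1 + L + pad - 1L
  y <- numeric(N)
  src_lo <- max(1L, lo); src_hi <- min(length(samples), hi)
  if (src_lo <= src_hi) y[(src_lo - lo + 1L):(src_hi - lo + 1L)] <- samples[src_lo:src_hi]
  cc <- Re(fft(Conj(fft(x)) * fft(y), inverse = TRUE)) / N
  lags <- lag_lo:lag_hi
  cc[(lags %% N) + 1L] / n_imp
}

#' Extract an averaged response waveform from EEG
#'
#' Implements the padded frequency-domain cross-correlation response estimate
#' trial by trial, then combines trials with Bayesian (inverse-variance) or
#' uniform weights. Trial weights are the inverse of the raw-EEG variance for
#' that trial, normalized to sum to one; pass `raw_variances` when the
#' recording given here has already been filtered and the weights should come
#' from the raw trace.
#'
#' @param eeg an [eeg_recording()] (typically after [preprocess()])
#' @param trials a list of per-trial [impulse_train()]s (one per trial
#'   boundary; indices are 0-based within the trial at any sampling rate —
#'   they are mapped to the EEG rate by the rounding rule of
#'   [downsample_impulses()]), or a single [impulse_train()] for a
#'   one-trial recording
#' @param lag_window_s stored lag window in seconds (default -0.5 to 0.6,
#'   wide enough for 40 prestimulus noise windows of 12 ms)
#' @param pad_s zero/surround padding on each side in seconds (default 1)
#' @param weighting `"bayesian"` (default) or `"uniform"`
#' @param raw_variances optional per-trial raw-EEG variances for the weights
#' @return a [response_waveform()]
#' @export
extract_response <- function(eeg, trials, lag_window_s = c(-0.5, 0.6),
                             pad_s = 1, weighting = c("bayesian", "uniform"),
                             raw_variances = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(eeg, "eeg_recording"))
  if (inherits(trials, "impulse_train")) trials <- list(trials)
  n_trials <- length(eeg$trial_boundaries)
  stopifnot(length(trials) == n_trials)
  fs <- eeg$fs_hz
  L <- round(eeg$token_duration_s * fs)
  pad <- as.integer(round(pad_s * fs))
  lag_lo <- as.integer(round(lag_window_s[1] * fs))
  lag_hi <- as.integer(round(lag_window_s[2] * fs))
  if (pad < lag_hi || pad < -lag_lo)
    abort("padding must cover the stored lag window")

  variances <- raw_variances %||% vapply(seq_len(n_trials), function(i) {
    s <- eeg$trial_boundaries[i]
    var(eeg$samples[s:(s + L - 1L)])
  }, numeric(1))
  if (weighting == "bayesian") {
    if (any(variances <= 0)) abort("degenerate trial: zero raw-EEG variance")
    lambda <- (1 / variances) / sum(1 / variances)
  } else {
    lambda <- rep(1 / n_trials, n_trials)
  }

  acc <- numeric(lag_hi - lag_lo + 1L)
  n_tot <- 0L
  for (i in seq_len(n_trials)) {
    tr <- trials[[i]]
    idx <- as.integer(round(tr$indices * fs / tr$fs_hz))
    idx <- idx[!duplicated(idx)]
    if (length(idx) == 0) abort("no stimuli in trial")
    wi <- xcorr_trial(eeg$samples, eeg$trial_boundaries[i], L, idx,
                      length(idx), pad, lag_lo, lag_hi)
    acc <- acc + lambda[i] * wi
    n_tot <- n_tot + length(idx)
  }
  response_waveform(acc, fs, lag_window_s, n_stimuli = n_tot,
                    n_trials = n_trials, condition = eeg$condition,
                    weights = lambda)
}

#' Extract per-trial response waveforms (no averaging)
#'
#' Same computation as [extract_response()] but returning one
#' [response_waveform()] per trial, with the per-trial raw variances
#' attached as an attribute — the inputs [weighted_average()] expects.
#'
#' @inheritParams extract_response
#' @return a list of [response_waveform()]s with attribute `variances`
#' @export
extract_trial_responses <- function(eeg, trials, lag_window_s = c(-0.5, 0.6),
                                    pad_s = 1) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (inherits(trials, "impulse_train")) trials <- list(trials)
  n_trials <- length(eeg$trial_boundaries)
  stopifnot(length(trials) == n_trials)
  fs <- eeg$fs_hz
  L <- round(eeg$token_duration_s * fs)
  pad <- as.integer(round(pad_s * fs))
  lag_lo <- as.integer(round(lag_window_s[1] * fs))
  lag_hi <- as.integer(round(lag_window_s[2] * fs))
  out <- vector("list", n_trials)
  variances <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- trials[[i]]
    idx <- as.integer(round(tr$indices * fs / tr$fs_hz))
    idx <- idx[!duplicated(idx)]
    if (length(idx) == 0) abort("no stimuli in trial")
    s <- eeg$trial_boundaries[i]
    variances[i] <- var(eeg$samples[s:(s + L - 1L)])
    wi <- xcorr_trial(eeg$samples, s, L, idx, length(idx), pad,
                      lag_lo, lag_hi)
    out[[i]] <- response_waveform(wi, fs, lag_window_s,
                                  n_stimuli = length(idx), n_trials = 1L,
                                  condition = eeg$condition)
  }
  attr(out, "variances") <- variances
  out
}

#' Inverse-variance trial weights
#'
#' Bayesian weighting: each trial's weight is the inverse of its raw-EEG
#' variance, normalized so the weights sum to one.
#'
#' @param variances positive per-trial raw-EEG variances
#' @return a tibble with columns `trial`, `variance`, `weight`
#' @export
trial_weights <- function(variances) {
  if (any(variances <= 0)) abort("degenerate trial: zero raw-EEG variance")
  w <- (1 / variances) / sum(1 / variances)
  tibble::tibble(trial = seq_along(variances), variance = variances,
                 weight = w)
}

#' Bayesian-weighted average of per-trial responses
#'
#' @param responses list of per-trial [response_waveform()]s (equal lag
#'   grids)
#' @param variances per-trial raw-EEG variances; defaults to the
#'   `variances` attribute of `responses`
#' @return a [response_waveform()]; equal variances reduce to the arithmetic
#'   mean
#' @export
weighted_average <- function(responses, variances = attr(responses, "variances")) {
  stopifnot(length(responses) >= 1, length(variances) == length(responses))
  w <- trial_weights(variances)$weight
  W <- vapply(responses, function(r) r$w, numeric(length(responses[[1]]$w)))
  r1 <- responses[[1]]
  response_waveform(as.numeric(W %*% w), r1$fs_hz, r1$lag_window_s,
                    n_stimuli = sum(vapply(responses, function(r)
                      r$n_stimuli, numeric(1))),
                    n_trials = length(responses), condition = r1$condition,
                    weights = w)
}
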