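#' Single-channel EEG recording container
#'
#' @param samples voltage series (volts)
#' @param fs_hz sampling rate (the standard EEG rate is 10 kHz)
#' @param trial_boundaries 1-based sample indices of trial (token) starts
#' @param token_duration_s trial length in seconds
#' @param condition list describing the stimulus condition
#' @param ground_truth optional list of embedded simulation parameters
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(samples, fs_hz, trial_boundaries,
                          token_duration_s = 1, condition = list(),
                          ground_truth = NULL) {
  stopifnot(all(is.finite(samples)), fs_hz > 0)
  structure(
    list(samples = as.numeric(samples), fs_hz = fs_hz,
         trial_boundaries = as.integer(trial_boundaries),
         token_duration_s = token_duration_s, condition = condition,
         ground_truth = ground_truth),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s), %d trials\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz,
              length(x$trial_boundaries)))
  invisible(x)
}

#' Effective per-band response gains for a condition
#'
#' Applies, in order: the excitation matrix row for the toneburst frequency;
#' high-pass-noise masking (bands at or above the cutoff are multiplied by
#' the masking residual epsilon); rate adaptation `(rate/20)^-exponent`; and,
#' under parallel presentation, suppression of off-frequency excitation that
#' ramps linearly with octave distance (saturating at one octave) and grows
#' with rate as `(rate/20)^suppression_rate_exponent`, capped at 0.95.
#'
#' @param model a [cochlear_band_model()]
#' @param stim_frequency_hz toneburst frequency (must be a model row)
#' @param rate_per_s stimulus rate
#' @param cutoff_hz high-pass-noise cutoff in Hz, or `"none"`
#' @param paradigm `"parallel"` or `"serial"`
#' @return named numeric vector of unitless gains, one per band
#' @export
band_gains <- function(model, stim_frequency_hz, rate_per_s, cutoff_hz,
                       paradigm = c("serial", "parallel")) {
  paradigm <- match.arg(paradigm)
  stopifnot(inherits(model, "cochlear_band_model"))
  key <- as.character(stim_frequency_hz)
  if (!key %in% rownames(model$A)) abort("missing bands for stimulus frequency")
  g <- model$A[key, ]
  bands <- model$band_centers_hz
  if (!identical(cutoff_hz, "none")) {
    masked <- bands >= cutoff_hz * 0.999  # nominal-grid tolerance
    g[masked] <- g[masked] * model$masking_residual
  }
  g <- g * (rate_per_s / 20)^(-model$adaptation_exponent)
  if (paradigm == "parallel") {
    p <- min(0.95, model$parallel_suppression *
               (rate_per_s / 20)^model$suppression_rate_exponent)
    offness <- pmin(1, abs(log2(bands / stim_frequency_hz)))
    g <- g * (1 - p * offness)
  }
  g
}

#' Draw per-trial impulse trains for a condition
#'
#' Draws `tokens` independent one-second token trains per frequency and
#' cycles them across `n_trials` trials (trial i uses token
#' `((i-1) mod tokens) + 1`), mirroring the reuse of a fixed token pool
#' during a recording run.
#'
#' @param frequencies_hz stimulus frequencies (vector)
#' @param rate_per_s stimulus rate
#' @param n_trials number of trials in the run
#' @param tokens size of the token pool (default 60)
#' @param token_duration_s token length in seconds (default 1)
#' @param fs_hz stimulus sampling rate (default 48000)
#' @param seed integer seed; expanded into per-frequency, per-token child
#'   seeds
#' @return named list (by frequency) of lists of [impulse_train()]s, one per
#'   trial
#' @export
draw_condition_trains <- function(frequencies_hz, rate_per_s, n_trials,
                                  tokens = 60, token_duration_s = 1,
                                  fs_hz = 48000, seed = 1) {
  out <- list()
  for (k in seq_along(frequencies_hz)) {
    pool <- lapply(seq_len(min(tokens, n_trials)), function(j)
      draw_impulse_train(rate_per_s, token_duration_s, fs_hz,
                         seed = child_seed(seed, k, j)))
    out[[as.character(frequencies_hz[k])]] <-
      pool[((seq_len(n_trials) - 1) %% length(pool)) + 1]
  }
  out
}

#' Forward-simulate EEG for one stimulus condition
#'
#' Builds `y = sum_f sum_b gain[f,b] * (train_f (*) kernel(latency_b)) +
#' noise`, where the gains come from [band_gains()] (masking, adaptation and
#' parallel suppression applied), the kernels are wave-V-like surrogates, and
#' the noise has per-trial log-normal variance heterogeneity. The neural
#' response is polarity-independent (both rarefaction and condensation
#' tonebursts evoke the same response); an optional electrical stimulus
#' artifact that *does* track polarity can be injected to exercise artifact
#' cancellation.
#'
#' @param condition list (or one-row data frame) with elements `paradigm`,
#'   `test_frequency_hz` (the frequency of interest; for parallel runs all
#'   trains are presented), `rate_per_s`, `cutoff_hz` (Hz or `"none"`), and
#'   `token_duration_s`
#' @param model a [cochlear_band_model()]
#' @param noise a [noise_model()]
#' @param trains named list (by frequency) of per-trial [impulse_train()]
#'   lists, as from [draw_condition_trains()]
#' @param seed integer seed for the noise stream
#' @param fs_eeg_hz EEG sampling rate (default 10000)
#' @param artifact_amplitude_v peak amplitude of the polarity-tracking
#'   stimulus artifact (default 0 = none)
#' @return an [eeg_recording()] with ground truth attached
#' @export
simulate_condition <- function(condition, model, noise, trains, seed = 1,
                               fs_eeg_hz = 10000, artifact_amplitude_v = 0) {
  stopifnot(inherits(model, "cochlear_band_model"),
            inherits(noise, "noise_model"))
  paradigm <- match.arg(condition$paradigm, c("serial", "parallel"))
  active <- if (paradigm == "serial")
    as.character(condition$test_frequency_hz) else names(trains)
  if (!all(active %in% names(trains)))
    abort("missing impulse trains for active frequencies")
  if (!all(active %in% rownames(model$A)))
    abort("missing bands: model lacks a row for an active frequency")
  n_trials <- length(trains[[active[1]]])
  tok_s <- condition$token_duration_s %||% 1
  L <- round(tok_s * fs_eeg_hz)
  n_total <- n_trials * L
  y <- numeric(n_total)

  gains <- list()
  for (f in active) {
    g <- band_gains(model, as.numeric(f), condition$rate_per_s,
                    condition$cutoff_hz, paradigm)
    gains[[f]] <- g
    # composite kernel: all band contributions for this stimulus frequency
    ks <- lapply(seq_along(g), function(b)
      wave_v_kernel(model$latency_ms[b], g[b] * model$response_peak_v,
                    fs_eeg_hz))
    lk <- max(vapply(ks, length, integer(1)))
    kern <- rowSums(vapply(ks, function(k) c(k, numeric(lk - length(k))),
                           numeric(lk)))
    idx_pol <- flatten_trains(trains[[f]], fs_eeg_hz, L)
    y <- add_kernel_at(y, idx_pol$indices, kern)
    if (artifact_amplitude_v != 0) {
      art <- wave_v_kernel(0.3, artifact_amplitude_v, fs_eeg_hz, width_ms = 0.6)
      y <- add_kernel_at(y, idx_pol$indices, art, weights = idx_pol$polarities)
    }
  }

  if (noise$base_std_v > 0 || noise$line_amplitude_v > 0) {
    y <- y + with_seed(seed, {
      # slowly drifting per-trial noise level: stationary AR(1) on the
      # log-std with marginal sd trial_sd_log
      rho <- noise$trial_ar %||% 0
      z <- rnorm(n_trials)
      l <- numeric(n_trials)
      if (n_trials > 0) l[1] <- z[1]
      for (i in seq_len(n_trials)[-1])
        l[i] <- rho * l[i - 1] + sqrt(1 - rho^2) * z[i]
      mult <- exp(noise$trial_sd_log * l)
      nz <- unlist(lapply(seq_len(n_trials), function(i) {
        e <- if (noise$spectrum == "white") rnorm(L) else pink_noise(L, fs_eeg_hz)
        s <- sd(e)
        if (s > 0) e * (noise$base_std_v * mult[i] / s) else e
      }))
      if (!is.null(noise$line_hz) && noise$line_amplitude_v > 0)
        nz <- nz + noise$line_amplitude_v *
          sin(2 * pi * noise$line_hz * (seq_len(n_total) - 1) / fs_eeg_hz)
      nz
    })
  }

  eeg_recording(
    y, fs_eeg_hz, trial_boundaries = (seq_len(n_trials) - 1L) * L + 1L,
    token_duration_s = tok_s,
    condition = condition[c("paradigm", "test_frequency_hz", "rate_per_s",
                            "cutoff_hz")],
    ground_truth = list(gains = gains, latency_ms = model$latency_ms,
                        band_centers_hz = model$band_centers_hz,
                        response_peak_v = model$response_peak_v, seed = seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten per-trial trains to global 0-based EEG-rate indices
#' @noRd
flatten_trains <- function(trial_trains, fs_eeg_hz, L) {
  idx <- integer(0); pol <- integer(0)
  for (i in seq_along(trial_trains)) {
    tr <- trial_trains[[i]]
    j <- as.integer(round(tr$indices * fs_eeg_hz / tr$fs_hz))
    keep <- !duplicated(j)
    idx <- c(idx, j[keep] + (i - 1L) * L)
    pol <- c(pol, tr$polarities[keep])
  }
  list(indices = idx, polarities = pol)
}

#' Add a kernel at each (unique) impulse index, vectorized over impulses
#' @noRd
add_kernel_at <- function(y, indices0, kernel, weights = NULL) {
  n <- length(y)
  for (j in seq_along(kernel)) {
    tgt <- indices0 + j
    ok <- tgt >= 1 & tgt <= n
    if (!any(ok)) next
    if (is.null(weights)) y[tgt[ok]] <- y[tgt[ok]] + kernel[j]
    else y[tgt[ok]] <- y[tgt[ok]] + weights[ok] * kernel[j]
  }
  y
}
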