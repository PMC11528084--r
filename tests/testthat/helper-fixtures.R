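# Shared fixtures: small, programmatically generated inputs.

# One-trial recording containing a single known kernel and optional noise.
kernel_recording <- function(latency_ms = 9, amplitude = 150e-9,
                             impulse_idx = 2000, fs = 10000,
                             duration_s = 1, noise_sd = 0, seed = 1) {
  k <- wave_v_kernel(latency_ms, amplitude, fs)
  y <- numeric(fs * duration_s)
  a <- impulse_idx + 1
  b <- min(length(y), a + length(k) - 1)
  y[a:b] <- k[seq_len(b - a + 1)]
  if (noise_sd > 0) y <- y + pabr:::with_seed(seed, rnorm(length(y), 0, noise_sd))
  tr <- impulse_train(impulse_idx, 1L, 1, duration_s, fs)
  list(eeg = eeg_recording(y, fs, 1L, token_duration_s = duration_s),
       train = tr, kernel = k)
}

# A response_waveform wrapping an arbitrary vector on the default lag grid.
waveform_from <- function(w, fs = 10000, lag_window_s = c(-0.5, 0.6),
                          condition = list()) {
  response_waveform(w, fs, lag_window_s, condition = condition)
}

# Deterministic "response + noise" waveform for estimator tests: a kernel
# placed at window_center_ms plus white noise across the whole lag span.
sized_waveform <- function(center_ms, within_window_sd, noise_sd, seed,
                           fs = 10000, lag_window_s = c(-0.5, 0.6)) {
  n <- round(diff(lag_window_s) * fs) + 1
  lag_ms <- seq(round(lag_window_s[1] * fs), round(lag_window_s[2] * fs)) / fs * 1000
  wl <- round(12 / 1000 * fs)
  ctr <- which.min(abs(lag_ms - center_ms))
  sel <- (ctr - wl %/% 2):(ctr + wl %/% 2 - 1)
  sig <- numeric(n)
  # one cosine cycle across the window, scaled to an exact within-window SD
  s0 <- cos(2 * pi * seq_along(sel) / length(sel))
  sig[sel] <- s0 * within_window_sd / sd(s0)
  noise <- pabr:::with_seed(seed, rnorm(n, 0, noise_sd))
  waveform_from(sig + noise, fs, lag_window_s)
}
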