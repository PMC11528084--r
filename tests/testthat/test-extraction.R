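test_that("preprocessing is causal, notched and validated", {
  fs <- 10000
  spec <- filter_spec()
  # notch list: odd multiples of 60 Hz up to 2500 Hz -> 21 notches
  expect_length(spec$notch_hz, 21)
  expect_equal(spec$notch_hz[1:3], c(60, 180, 300))
  expect_equal(max(spec$notch_hz), 2460)
  expect_true(all((spec$notch_hz / 60) %% 2 == 1))
  # zero in, zero out
  z <- eeg_recording(numeric(fs), fs, 1L)
  expect_true(all(preprocess(z)$samples == 0))
  # steady-state 60 Hz attenuation of at least 20 dB
  t <- (0:(10 * fs - 1)) / fs
  hum <- eeg_recording(sin(2 * pi * 60 * t), fs, 1L, token_duration_s = 10)
  out <- preprocess(hum)$samples
  ss <- out[(5 * fs):(10 * fs)]
  expect_lt(20 * log10(max(abs(ss))), -20)
  # sampling-rate mismatch is an error
  bad <- eeg_recording(numeric(8000), 8000, 1L)
  expect_error(preprocess(bad), "mismatch")
})

test_that("impulse downsampling follows the rounding rule and merges collisions", {
  tr <- impulse_train(c(0L, 4800L), c(1L, -1L), 40, 1, 48000)
  ds <- downsample_impulses(tr, 10000)
  expect_equal(ds$indices, c(0L, 1000L))
  expect_equal(ds$fs_hz, 10000)
  # two stimulus-rate indices mapping to one EEG sample collapse to a single
  # unit impulse, with a warning
  coll <- impulse_train(c(10L, 12L), c(1L, 1L), 100, 1, 48000)
  expect_warning(ds2 <- downsample_impulses(coll, 10000), "collision")
  expect_equal(ds2$indices, 2L)
  expect_equal(ds2$n, 1L)
  # collisions are plausible at 100/s over a long token: property check that
  # n never increases and indices stay strictly increasing
  for (s in 1:5) {
    big <- draw_impulse_train(100, 10, 48000, seed = s)
    dsb <- suppressWarnings(downsample_impulses(big, 10000))
    expect_lte(dsb$n, big$n)
    expect_false(is.unsorted(dsb$indices, strictly = TRUE))
  }
})

test_that("frequency-domain extraction equals direct epoch averaging", {
  fs <- 10000
  m <- cochlear_band_model()
  tr <- draw_impulse_train(40, 10, 48000, seed = 31)
  cond <- list(paradigm = "serial", test_frequency_hz = 1000, rate_per_s = 40,
               cutoff_hz = "none", token_duration_s = 10)
  eeg <- simulate_condition(cond, m, noise_model(base_std_v = 2e-6),
                            list(`1000` = list(tr)), seed = 32)
  w <- extract_response(eeg, tr, weighting = "uniform")
  # brute-force oracle: average epochs cut around each impulse, with zeros
  # beyond the recording
  idx <- unique(round(tr$indices * fs / 48000))
  lag_lo <- -5000; lag_hi <- 6000
  padded <- c(numeric(fs), eeg$samples, numeric(fs))
  epochs <- vapply(idx, function(i) padded[fs + i + 1 + (lag_lo:lag_hi)],
                   numeric(lag_hi - lag_lo + 1))
  oracle <- rowMeans(epochs)
  expect_lt(sqrt(sum((w$w - oracle)^2) / sum(oracle^2)), 1e-9)
})

test_that("padding with the surrounding EEG kills circular artifacts", {
  fs <- 10000
  # token with impulses whose epochs are interior to the token
  set.seed(41)
  tok <- rnorm(2 * fs, 0, 1e-6)
  idx <- sort(sample(5000:14000, 40))
  idx <- idx[!duplicated(idx)]
  tr <- impulse_train(idx, rep(c(1L, -1L), length.out = length(idx)), 20, 2, fs)
  iso <- eeg_recording(tok, fs, 1L, token_duration_s = 2)
  w_iso <- extract_response(iso, tr, weighting = "uniform")
  # same token embedded mid-session between unrelated EEG stretches
  sess <- c(rnorm(fs, 0, 1e-6), tok, rnorm(fs, 0, 1e-6))
  emb <- eeg_recording(sess, fs, fs + 1L, token_duration_s = 2)
  w_emb <- extract_response(emb, tr, weighting = "uniform")
  expect_lt(max(abs(w_iso$w - w_emb$w)), 1e-9 * max(abs(w_iso$w)))
})

test_that("doubling n with identical epochs leaves the response unchanged", {
  fs <- 10000
  k <- wave_v_kernel(9, 100e-9, fs)
  y <- numeric(3 * fs)
  for (i0 in c(7000, 20000)) y[i0 + seq_along(k)] <- k
  eeg <- eeg_recording(y, fs, 1L, token_duration_s = 3)
  w1 <- extract_response(eeg, impulse_train(7000, 1L, 1, 3, fs),
                         weighting = "uniform")
  w2 <- extract_response(eeg, impulse_train(c(7000, 20000), c(1L, -1L), 1, 3, fs),
                         weighting = "uniform")
  expect_equal(w2$w, w1$w, tolerance = 1e-12)
  expect_equal(w2$n_stimuli, 2L)
  # empty train errors
  expect_error(extract_response(eeg, impulse_train(integer(0), integer(0),
                                                   0, 3, fs)),
               "no stimuli")
})

test_that("inverse-variance weights are normalized and correct in closed form", {
  tw <- trial_weights(c(1, 4))
  expect_equal(tw$weight, c(0.8, 0.2))
  rand_vars <- pabr:::with_seed(5, runif(17, 0.2, 9))
  expect_equal(sum(trial_weights(rand_vars)$weight), 1, tolerance = 1e-12)
  expect_error(trial_weights(c(1, 0)), "degenerate")
  # equal variances reduce the weighted average to the arithmetic mean
  fs <- 10000
  resp <- lapply(1:3, function(i)
    response_waveform(pabr:::with_seed(i, rnorm(11001)), fs))
  wavg <- weighted_average(resp, c(2, 2, 2))
  expect_equal(wavg$w, rowMeans(vapply(resp, function(r) r$w, numeric(11001))),
               tolerance = 1e-12)
})

test_that("Bayesian weighting beats uniform averaging under heteroscedastic noise", {
  fs <- 10000
  k <- wave_v_kernel(9, 100e-9, fs)
  sig <- numeric(11001)
  sig[5001 + seq_along(k)] <- k  # response at positive lags only
  wins <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    resp <- list()
    vars <- numeric(8)
    pabr:::with_seed(s, {
      mult <- exp(rnorm(8, 0, 0.5))
      for (i in 1:8) {
        noise <- rnorm(11001, 0, 100e-9 * mult[i])
        resp[[i]] <- response_waveform(sig + noise, fs)
        vars[i] <- var(noise)
      }
    })
    wa <- weighted_average(resp, vars)
    ua <- weighted_average(resp, rep(1, 8))
    pre <- wa$lag_ms < 0
    if (var(wa$w[pre]) < var(ua$w[pre])) wins <- wins + 1
  }
  expect_gte(wins, 90)
})

test_that("polarity-balanced stimulus artifact cancels in the average", {
  m0 <- cochlear_band_model(response_peak_v = 0)  # artifact only
  trains <- draw_condition_trains(500, 40, 60, fs_hz = 48000, seed = 51)
  cond <- list(paradigm = "serial", test_frequency_hz = 500, rate_per_s = 40,
               cutoff_hz = "none", token_duration_s = 1)
  eeg <- simulate_condition(cond, m0, noise_model(base_std_v = 0), trains,
                            seed = 52, artifact_amplitude_v = 1e-6)
  w <- extract_response(eeg, trains[["500"]], weighting = "uniform")
  # single-trial artifact amplitude is 1 uV; the rectified average must
  # attenuate it by at least 40 dB
  expect_lt(max(abs(w$w)), 1e-6 * 10^(-40 / 20))
})
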