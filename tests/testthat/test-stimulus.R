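test_that("tonebursts have the right length, spectrum, level and DC", {
  tb <- make_toneburst(toneburst_spec(2000, n_cycles = 5, sample_rate_hz = 48000))
  expect_length(tb, 120)
  # spectral peak at the toneburst frequency
  spec <- abs(fft(c(as.numeric(tb), numeric(48000 - length(tb)))))[1:24000]
  expect_equal(which.max(spec) - 1, 2000)
  # peak equivalence: toneburst peak equals the peak of a 75 dB peSPL
  # reference sinusoid under the digital convention, within 0.1 dB
  ref_peak <- max(abs(sin(2 * pi * 2000 * (0:47999) / 48000))) * 10^((75 - 110) / 20)
  expect_lt(abs(20 * log10(max(abs(tb)) / ref_peak)), 0.1)
  # near-zero DC
  expect_lt(abs(mean(tb)), 1e-4 * max(abs(tb)))
  # silent level gives an all-zero waveform
  tb0 <- make_toneburst(toneburst_spec(2000, level_db_pespl = -Inf))
  expect_true(all(tb0 == 0))
  # every envelope choice produces a valid burst of the same length
  for (env in c("hann", "cosine-squared")) {
    tbe <- make_toneburst(toneburst_spec(500, envelope = env))
    expect_length(tbe, 480)
    expect_true(all(is.finite(tbe)))
  }
  expect_error(make_toneburst(toneburst_spec(30000, sample_rate_hz = 48000)),
               "unrepresentable")
})

test_that("Poisson impulse trains have correct counts and polarity balance", {
  # count concentration: rate 40 over 60 s within 3 sd of 2400
  tr <- draw_impulse_train(40, 60, seed = 101)
  expect_gt(tr$n, 2400 - 3 * sqrt(2400))
  expect_lt(tr$n, 2400 + 3 * sqrt(2400))
  expect_false(is.unsorted(tr$indices, strictly = TRUE))
  # exact-half polarity split
  for (s in 1:20) {
    tri <- draw_impulse_train(100, 1, seed = s)
    expect_true(sum(tri$polarities) %in% c(-1L, 0L, 1L))
  }
  # long-run mean count approaches rate * duration (property over seeds)
  counts <- vapply(1:50, function(s) draw_impulse_train(20, 1, seed = s)$n,
                   numeric(1))
  se <- sqrt(20 / 50)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  # degenerate cases
  expect_equal(draw_impulse_train(0, 1, seed = 1)$n, 0)
  expect_error(draw_impulse_train(-5, 1), "negative")
})

test_that("assembled stimuli obey the parallel/serial relationship", {
  fs <- 48000
  freqs <- c(500, 1000, 2000, 4000, 8000)
  tbs <- lapply(freqs, function(f) make_toneburst(toneburst_spec(f)))
  names(tbs) <- freqs
  trains <- lapply(seq_along(freqs), function(i)
    draw_impulse_train(40, 1, fs, seed = 200 + i))
  names(trains) <- freqs
  par5 <- assemble_stimulus(trains, tbs, "parallel")
  ser <- assemble_stimulus(trains, tbs, "serial", serial_frequency_hz = 2000)
  # serial token is bit-identical to the matching single train of the ensemble
  only2000 <- trains
  for (f in setdiff(names(trains), "2000"))
    only2000[[f]] <- impulse_train(integer(0), integer(0), 40, 1, fs)
  expect_identical(as.numeric(assemble_stimulus(only2000, tbs, "parallel")),
                   as.numeric(ser))
  # more active frequencies -> larger RMS
  expect_gt(sqrt(mean(par5^2)), sqrt(mean(ser^2)))
  # single impulse reproduces the shifted toneburst exactly
  k <- 1000L
  tr1 <- list(`2000` = impulse_train(k, 1L, 1, 1, fs))
  tok <- assemble_stimulus(tr1, tbs["2000"], "serial", serial_frequency_hz = 2000)
  expect_equal(as.numeric(tok[(k + 1):(k + 120)]), as.numeric(tbs[["2000"]]),
               tolerance = 1e-12)
  expect_true(all(tok[seq_len(k)] == 0))
  # mismatched sample rates error
  bad <- trains
  bad[["500"]] <- draw_impulse_train(40, 1, 44100, seed = 1)
  expect_error(assemble_stimulus(bad, tbs, "parallel"), "sample rate")
})

test_that("high-pass pink-noise maskers meet spectral requirements", {
  fs <- 48000
  mk <- make_hpn_masker(masker_spec(cutoff_hz = 250, sample_rate_hz = fs),
                        duration_s = 4, seed = 5)
  psd <- welch_psd(as.numeric(mk), fs, 8192)
  p125 <- mean(psd$psd[psd$frequency_hz >= 100 & psd$frequency_hz <= 150])
  p1k <- mean(psd$psd[psd$frequency_hz >= 900 & psd$frequency_hz <= 1100])
  expect_lt(10 * log10(p125 / p1k), -60)
  # full-band pink noise: log-log PSD slope about -3 dB/octave
  pk <- make_hpn_masker(masker_spec(cutoff_hz = "none", sample_rate_hz = fs),
                        duration_s = 4, seed = 6)
  psd2 <- welch_psd(as.numeric(pk), fs, 8192)
  sel <- psd2$frequency_hz >= 100 & psd2$frequency_hz <= 10000
  fit <- stats::lm(log2(psd2$psd[sel]) ~ log2(psd2$frequency_hz[sel]))
  slope_db_oct <- 10 * log10(2) * coef(fit)[2]
  expect_lt(abs(slope_db_oct - (-3)), 0.5)
  # 69 vs 72 dB SPL: digital gains differ by exactly 3 dB
  a <- make_hpn_masker(masker_spec(level_db_spl = 69), 1, seed = 7)
  b <- make_hpn_masker(masker_spec(level_db_spl = 72), 1, seed = 7)
  expect_equal(20 * log10(sd(b) / sd(a)), 3, tolerance = 1e-9)
  expect_error(masker_spec(cutoff_hz = 30000, sample_rate_hz = fs), "Nyquist")
})

test_that("condition grids and band-center labels match the study design", {
  par <- enumerate_conditions("parallel")
  expect_equal(nrow(par), 13)
  expect_equal(par$cutoff_hz[1], 250L)
  expect_equal(par$cutoff_hz[13], 16000L)
  s500 <- enumerate_conditions("serial", 500)
  expect_equal(nrow(s500), 7)
  expect_equal(range(s500$cutoff_hz), c(250L, 2000L))
  expect_equal(enumerate_conditions("serial", 2000)$cutoff_hz,
               c(1000L, 1414L, 2000L, 2828L, 4000L, 5657L, 8000L))
  expect_error(enumerate_conditions("serial"), "test frequency")
  expect_equal(derived_band_center(707, 1414), 1000L)
  expect_equal(derived_band_center(250, 500), 354L)
  # closed form before rounding: sqrt(f * 2f) = f * sqrt(2)
  expect_equal(sqrt(600 * 1200), 600 * sqrt(2))
  expect_error(derived_band_center(500, 1414), "octave")
  plan <- session_plan()
  expect_equal(plan$total_min, 600)
  expect_equal(plan$minutes_per_condition, 10)
})
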