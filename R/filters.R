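#' EEG preprocessing filter specification
#'
#' Causal filtering only: a first-order Butterworth bandpass between 30 and
#' 2000 Hz followed by causal IIR notch filters at odd integer multiples of
#' the mains frequency up to `notch_max_hz`, each with a 5 Hz bandwidth.
#' Causal (not zero-phase) filtering shifts latencies identically across
#' conditions, so latency comparisons remain valid.
#'
#' @param bandpass_hz two-element vector of band edges (default `c(30, 2000)`)
#' @param order Butterworth order of the bandpass (default 1)
#' @param line_hz mains frequency (default 60)
#' @param notch_max_hz notch multiples of `line_hz` up to this frequency are
#'   applied (default 2500)
#' @param notch_bandwidth_hz -3 dB bandwidth of each notch (default 5)
#' @param fs_hz expected EEG sampling rate (default 10000)
#' @return an object of class `filter_spec`; its `notch_hz` element lists the
#'   notch frequencies (60, 180, ..., 2460 Hz for the defaults: 21 notches)
#' @export
filter_spec <- function(bandpass_hz = c(30, 2000), order = 1, line_hz = 60,
                        notch_max_hz = 2500, notch_bandwidth_hz = 5,
                        fs_hz = 10000) {
  k <- seq(1, floor(notch_max_hz / line_hz), by = 2)
  structure(
    list(bandpass_hz = bandpass_hz, order = order, line_hz = line_hz,
         notch_hz = line_hz * k, notch_bandwidth_hz = notch_bandwidth_hz,
         fs_hz = fs_hz),
    class = "filter_spec"
  )
}

#' Causal direct-form IIR filter (b, a coefficients)
#'
#' Zero initial conditions; numerator via one-sided convolution, denominator
#' via the recursive filter, both in C through [stats::filter()].
#' @noRd
iir_filter <- function(b, a, x) {
  n <- length(x)
  b <- b / a[1]
  xf <- b[1] * x
  for (j in seq_len(length(b) - 1))
    xf[(j + 1):n] <- xf[(j + 1):n] + b[j + 1] * x[1:(n - j)]
  if (length(a) > 1)
    xf <- as.numeric(stats::filter(xf, -a[-1] / a[1], method = "recursive"))
  xf
}

#' Design a causal IIR notch biquad
#' @noRd
notch_biquad <- function(f0, bw, fs) {
  w0 <- 2 * pi * f0 / fs
  r <- 1 - pi * bw / fs
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  g <- sum(a) / sum(b)  # unity gain at DC
  list(b = b * g, a = a)
}

#' Preprocess raw EEG
#'
#' Applies the causal bandpass then each notch filter in sequence. No
#' zero-phase filtering is used.
#'
#' @param eeg an [eeg_recording()]
#' @param spec a [filter_spec()]; its `fs_hz` must match the recording
#' @return a filtered [eeg_recording()]
#' @export
preprocess <- function(eeg, spec = filter_spec()) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(eeg$fs_hz, spec$fs_hz)))
    abort("sampling-rate mismatch between recording and filter specification")
  fs <- eeg$fs_hz
  bf <- signal::butter(spec$order, spec$bandpass_hz / (fs / 2), type = "pass")
  x <- iir_filter(as.numeric(bf$b), as.numeric(bf$a), eeg$samples)
  for (f0 in spec$notch_hz) {
    nb <- notch_biquad(f0, spec$notch_bandwidth_hz, fs)
    x <- iir_filter(nb$b, nb$a, x)
  }
  out <- eeg
  out$samples <- x
  out
}
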