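#' Toneburst specification
#'
#' Describes a brief windowed sinusoid used as a frequency-specific ABR
#' stimulus. Duration is `n_cycles / frequency_hz`. Level follows the
#' package's digital convention (a full-scale sinusoid is 110 dB SPL): the
#' toneburst peak is scaled to equal the peak of a reference sinusoid at
#' `level_db_pespl`.
#'
#' @param frequency_hz toneburst frequency in Hz (the standard set is 500,
#'   1000, 2000, 4000 and 8000 Hz, but any frequency below Nyquist is allowed)
#' @param n_cycles number of sinusoid cycles (default 5)
#' @param envelope window shape: `"blackman"` (default), `"hann"` or
#'   `"cosine-squared"`
#' @param level_db_pespl presentation level in dB peSPL, digital convention
#'   (default 75); `-Inf` gives a silent burst
#' @param sample_rate_hz audio sampling rate in Hz (default 48000)
#' @return an object of class `toneburst_spec`
#' @export
toneburst_spec <- function(frequency_hz, n_cycles = 5,
                           envelope = c("blackman", "hann", "cosine-squared"),
                           level_db_pespl = 75, sample_rate_hz = 48000) {
  envelope <- match.arg(envelope)
  stopifnot(frequency_hz > 0, n_cycles >= 1, sample_rate_hz > 0)
  structure(
    list(frequency_hz = frequency_hz, n_cycles = as.integer(n_cycles),
         envelope = envelope, level_db_pespl = level_db_pespl,
         sample_rate_hz = sample_rate_hz),
    class = "toneburst_spec"
  )
}

#' Synthesize a toneburst waveform
#'
#' Returns a windowed sinusoid of duration `n_cycles / frequency_hz`, scaled
#' so that its peak equals the peak of a reference sinusoid at the requested
#' dB peSPL level (peak equivalence). The integer-cycle windowed sinusoid has
#' essentially zero DC.
#'
#' @param spec a [toneburst_spec()]
#' @return a numeric waveform with attributes `fs_hz` and `spec`
#' @export
make_toneburst <- function(spec) {
  stopifnot(inherits(spec, "toneburst_spec"))
  f <- spec$frequency_hz
  fs <- spec$sample_rate_hz
  if (f >= fs / 2) abort("unrepresentable toneburst: frequency at or above Nyquist")
  n <- round(fs * spec$n_cycles / f)
  t <- (seq_len(n) - 1) / fs
  win <- switch(spec$envelope,
    "blackman" = 0.42 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) +
      0.08 * cos(4 * pi * (seq_len(n) - 1) / (n - 1)),
    "hann" = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
    "cosine-squared" = sin(pi * (seq_len(n) - 1) / (n - 1))^2
  )
  w <- sin(2 * pi * f * t) * win
  target_peak <- db_to_peak(spec$level_db_pespl)
  pk <- max(abs(w))
  w <- if (target_peak == 0 || pk == 0) w * 0 else w * (target_peak / pk)
  structure(w, fs_hz = fs, spec = spec)
}
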