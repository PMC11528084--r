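#' Assemble a stimulus token from impulse trains and tonebursts
#'
#' Convolves each frequency's impulse train with its toneburst (a sparse
#' placement of signed toneburst copies) and, under parallel presentation,
#' sums across frequencies. Under serial presentation a single frequency's
#' train is presented in isolation; a serial token is bit-identical to the
#' corresponding single train extracted from the parallel ensemble when the
#' seeds match.
#'
#' @param trains named list of [impulse_train()]s, one per stimulus frequency
#'   (names are frequencies in Hz)
#' @param tonebursts named list of waveforms from [make_toneburst()], matching
#'   `names(trains)`
#' @param paradigm `"parallel"` (sum all trains) or `"serial"`
#' @param serial_frequency_hz for `paradigm = "serial"`, the frequency (name)
#'   to present in isolation
#' @return a numeric audio token with attribute `fs_hz`
#' @export
assemble_stimulus <- function(trains, tonebursts,
                              paradigm = c("parallel", "serial"),
                              serial_frequency_hz = NULL) {
  paradigm <- match.arg(paradigm)
  stopifnot(length(trains) >= 1, all(names(trains) %in% names(tonebursts)))
  fs <- unique(vapply(trains, function(tr) tr$fs_hz, numeric(1)))
  dur <- unique(vapply(trains, function(tr) tr$duration_s, numeric(1)))
  if (length(fs) != 1 || length(dur) != 1)
    abort("all impulse trains must share sample rate and duration")
  for (nm in names(trains))
    if (!isTRUE(all.equal(attr(tonebursts[[nm]], "fs_hz"), fs)))
      abort("toneburst and impulse-train sample rates differ")
  active <- if (paradigm == "serial") {
    if (is.null(serial_frequency_hz))
      abort("serial paradigm requires serial_frequency_hz")
    as.character(serial_frequency_hz)
  } else names(trains)
  if (!all(active %in% names(trains))) abort("requested frequency has no train")
  n_tok <- round(fs * dur)
  y <- numeric(n_tok)
  for (nm in active) {
    tr <- trains[[nm]]
    tb <- as.numeric(tonebursts[[nm]])
    lt <- length(tb)
    for (i in seq_len(tr$n)) {
      a <- tr$indices[i] + 1L
      b <- min(a + lt - 1L, n_tok)
      if (a > n_tok) next
      y[a:b] <- y[a:b] + tr$polarities[i] * tb[seq_len(b - a + 1L)]
    }
  }
  structure(y, fs_hz = fs)
}

#' High-pass noise masker specification
#'
#' @param cutoff_hz high-pass cutoff in Hz, or `"none"` for full-band pink
#'   noise
#' @param spectrum noise color; only `"pink"` (1/f power) is implemented
#' @param level_db_spl RMS level in dB SPL under the digital convention
#'   (the standard levels are 69 and 72)
#' @param filter_order Butterworth order of one pass (default 8); the
#'   magnitude response is applied twice (zero phase), giving roughly
#'   96 dB/octave of attenuation below the cutoff
#' @param sample_rate_hz audio sampling rate in Hz
#' @return an object of class `masker_spec`
#' @export
masker_spec <- function(cutoff_hz = "none", spectrum = "pink",
                        level_db_spl = 69, filter_order = 8,
                        sample_rate_hz = 48000) {
  spectrum <- match.arg(spectrum)
  if (!identical(cutoff_hz, "none")) {
    stopifnot(is.numeric(cutoff_hz), cutoff_hz > 0)
    if (cutoff_hz >= sample_rate_hz / 2)
      abort("masker cutoff at or above Nyquist")
  }
  structure(
    list(cutoff_hz = cutoff_hz, spectrum = spectrum,
         level_db_spl = level_db_spl, filter_order = filter_order,
         sample_rate_hz = sample_rate_hz),
    class = "masker_spec"
  )
}

#' Generate a high-pass pink-noise masker token
#'
#' Pink noise is synthesized spectrally (amplitude proportional to 1/sqrt(f))
#' and shaped by the squared magnitude response of an 8th-order Butterworth
#' high-pass filter — the zero-phase equivalent of a forward-backward pass —
#' then scaled so its RMS matches `level_db_spl` under the digital level
#' convention. Power one octave below the cutoff is more than 60 dB below the
#' passband.
#'
#' @param spec a [masker_spec()]
#' @param duration_s token length in seconds (default 1)
#' @param seed optional integer seed
#' @return a numeric audio token with attributes `fs_hz` and `spec`
#' @export
make_hpn_masker <- function(spec, duration_s = 1, seed = NULL) {
  stopifnot(inherits(spec, "masker_spec"), duration_s > 0)
  fs <- spec$sample_rate_hz
  n <- round(fs * duration_s)
  cutoff <- if (identical(spec$cutoff_hz, "none")) NULL else spec$cutoff_hz
  x <- pink_noise(n, fs, cutoff_hz = cutoff, order = spec$filter_order,
                  seed = seed)
  target_rms <- db_to_rms(spec$level_db_spl)
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x * (target_rms / r)
  structure(x, fs_hz = fs, spec = spec)
}
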