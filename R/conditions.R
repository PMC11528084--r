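#' Nominal half-octave frequency grid
#'
#' Frequencies spaced in half-octave steps, rounded to the conventional
#' nominal values (250, 354, 500, 707, 1000, 1414, 2000, 2828, 4000, 5657,
#' 8000, 11314, 16000 Hz for the standard span).
#'
#' @param from,to span endpoints in Hz; `to` must be `from` times a power of
#'   sqrt(2) (within rounding)
#' @return integer vector of nominal frequencies
#' @export
half_octave_grid <- function(from = 250, to = 16000) {
  n_steps <- round(2 * log2(to / from))
  stopifnot(n_steps >= 0)
  as.integer(round(from * 2^(seq(0, n_steps) / 2)))
}

#' Enumerate masker conditions for a paradigm
#'
#' Parallel presentation uses high-pass noise cutoffs spanning 250 to
#' 16000 Hz in half-octave steps (13 conditions). Serial presentation spans
#' one octave below to two octaves above the test frequency (7 conditions).
#'
#' @param paradigm `"parallel"` or `"serial"`
#' @param test_frequency_hz required for serial: one of 500, 1000, 2000,
#'   4000, 8000
#' @param tokens number of one-second stimulus/noise tokens per condition
#'   (default 60)
#' @param token_duration_s token length in seconds (default 1)
#' @return a tibble with one row per high-pass cutoff, columns `paradigm`,
#'   `test_frequency_hz`, `cutoff_hz` (nominal), `cutoff_exact_hz`, `tokens`,
#'   `token_duration_s`
#' @export
enumerate_conditions <- function(paradigm = c("parallel", "serial"),
                                 test_frequency_hz = NULL, tokens = 60,
                                 token_duration_s = 1) {
  paradigm <- match.arg(paradigm)
  if (paradigm == "parallel") {
    from <- 250; to <- 16000
    test_frequency_hz <- NA_real_
  } else {
    if (is.null(test_frequency_hz))
      abort("serial paradigm requires a test frequency")
    if (!test_frequency_hz %in% c(500, 1000, 2000, 4000, 8000))
      abort("serial test frequency must be one of 500, 1000, 2000, 4000, 8000 Hz")
    from <- test_frequency_hz / 2
    to <- 4 * test_frequency_hz
  }
  n_steps <- round(2 * log2(to / from))
  exact <- from * 2^(seq(0, n_steps) / 2)
  tibble::tibble(
    paradigm = paradigm,
    test_frequency_hz = test_frequency_hz,
    cutoff_hz = as.integer(round(exact)),
    cutoff_exact_hz = exact,
    tokens = as.integer(tokens),
    token_duration_s = token_duration_s
  )
}

#' Center frequency label of a derived band
#'
#' Derived bands are named by the geometric mean of the two high-pass noise
#' cutoffs used to construct them (e.g. the 707 to 1414 Hz band is denoted
#' 1000 Hz), snapped to the nominal half-octave grid.
#'
#' @param cutoff_low,cutoff_high the two cutoffs in Hz; they must be one
#'   octave apart (within the grid's nominal rounding)
#' @return the nominal band-center frequency in Hz (integer)
#' @export
derived_band_center <- function(cutoff_low, cutoff_high) {
  stopifnot(cutoff_low > 0, cutoff_high > 0)
  if (abs(log2(cutoff_high / cutoff_low) - 1) > 0.02)
    abort("non-octave pair: cutoffs must be one octave apart")
  gm <- sqrt(cutoff_low * cutoff_high)
  grid <- round(1000 * 2^(seq(-10, 10) / 2))
  as.integer(grid[which.min(abs(log2(grid / gm)))])
}

#' Recording-session arithmetic
#'
#' Splits a multi-session recording budget across masker conditions and
#' stimulus rates. The standard layout — 4 sessions of 150 minutes over 20
#' masker conditions (13 parallel + 7 per-frequency serial) at 3 rates —
#' gives 600 minutes total and 10 minutes per condition.
#'
#' @param n_sessions number of recording sessions (default 4)
#' @param minutes_per_session minutes of stimuli per session (default 150)
#' @param n_masker_conditions number of high-pass-noise conditions (default
#'   20)
#' @param n_rates number of stimulus rates (default 3)
#' @return a one-row tibble with `total_min`, `n_conditions` and
#'   `minutes_per_condition`
#' @export
session_plan <- function(n_sessions = 4, minutes_per_session = 150,
                         n_masker_conditions = 20, n_rates = 3) {
  stopifnot(n_sessions > 0, minutes_per_session > 0)
  total <- n_sessions * minutes_per_session
  n_cond <- n_masker_conditions * n_rates
  tibble::tibble(
    n_sessions = as.integer(n_sessions),
    minutes_per_session = minutes_per_session,
    total_min = total,
    n_conditions = as.integer(n_cond),
    minutes_per_condition = total / n_cond
  )
}
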