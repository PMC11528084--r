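#' Construct an impulse-train object
#'
#' Low-level constructor; most users call [draw_impulse_train()]. Indices are
#' 0-based sample offsets at `fs_hz` and must be strictly increasing.
#'
#' @param indices 0-based sample indices, strictly increasing
#' @param polarities per-impulse signs in `{+1, -1}`
#' @param rate_per_s nominal Poisson rate (stimuli per second)
#' @param duration_s token duration in seconds
#' @param fs_hz sampling rate of the index grid
#' @param seed the seed used to draw the train (or `NA`)
#' @return an object of class `impulse_train`
#' @export
impulse_train <- function(indices, polarities, rate_per_s, duration_s, fs_hz,
                          seed = NA_integer_) {
  indices <- as.integer(indices)
  polarities <- as.integer(polarities)
  stopifnot(length(indices) == length(polarities),
            all(polarities %in% c(-1L, 1L)),
            !is.unsorted(indices, strictly = TRUE) || length(indices) <= 1)
  structure(
    list(indices = indices, polarities = polarities,
         rate_per_s = rate_per_s, duration_s = duration_s, fs_hz = fs_hz,
         n = length(indices), seed = seed),
    class = "impulse_train"
  )
}

#' Draw a Poisson-timed impulse train
#'
#' Event times follow a homogeneous Poisson process at `rate_per_s`,
#' quantized to sample indices (coincident events are merged). Exactly half
#' of the impulses (floor(n/2) when n is odd) are assigned negative polarity
#' by a seeded shuffle, producing rarefaction/condensation pairs whose
#' electrical stimulus artifact cancels in the rectified average.
#'
#' @param rate_per_s Poisson rate in stimuli per second (the standard rates
#'   are 20, 40 and 100)
#' @param duration_s token duration in seconds (default 1)
#' @param fs_hz sampling rate of the index grid (default 48000)
#' @param seed optional integer seed
#' @return an [impulse_train()]
#' @export
draw_impulse_train <- function(rate_per_s, duration_s = 1, fs_hz = 48000,
                               seed = NULL) {
  if (rate_per_s < 0) abort("negative stimulus rate")
  with_seed(seed, {
    n_events <- rpois(1, rate_per_s * duration_s)
    idx <- sort(unique(as.integer(floor(runif(n_events, 0, duration_s) * fs_hz))))
    n <- length(idx)
    pol <- rep(1L, n)
    # exact half flipped; for odd n the extra impulse's sign is randomized
    # (floor or ceil) so the leftover artifact has zero expectation
    if (n > 0) {
      n_neg <- n %/% 2L + if (n %% 2L == 1L) stats::rbinom(1, 1, 0.5) else 0L
      pol[sample.int(n, n_neg)] <- -1L
    }
    impulse_train(idx, pol, rate_per_s, duration_s, fs_hz,
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Downsample impulse indices to the EEG sampling rate
#'
#' Each index is multiplied by the EEG sampling rate, divided by the stimulus
#' sampling rate, and rounded to the nearest integer. All impulses keep
#' magnitude 1; if two stimulus-rate impulses land on the same EEG sample the
#' collision collapses to a single unit impulse and a warning reports the
#' count.
#'
#' @param train an [impulse_train()]
#' @param fs_eeg_hz target (EEG) sampling rate, default 10000
#' @return an [impulse_train()] on the EEG index grid
#' @export
downsample_impulses <- function(train, fs_eeg_hz = 10000) {
  stopifnot(inherits(train, "impulse_train"), fs_eeg_hz > 0, train$fs_hz > 0)
  idx <- as.integer(round(train$indices * fs_eeg_hz / train$fs_hz))
  keep <- !duplicated(idx)
  n_coll <- sum(!keep)
  if (n_coll > 0)
    warn(sprintf("%d impulse collision(s) merged during downsampling", n_coll))
  impulse_train(idx[keep], train$polarities[keep], train$rate_per_s,
                train$duration_s, fs_eeg_hz, seed = train$seed)
}

#' @export
print.impulse_train <- function(x, ...) {
  cat(sprintf(
    "<impulse_train> n = %d, rate = %g /s, duration = %g s, fs = %g Hz\n",
    x$n, x$rate_per_s, x$duration_s, x$fs_hz))
  invisible(x)
}

#' Tidy an impulse train into a tibble
#'
#' @param x an [impulse_train()]
#' @param ... unused
#' @return a tibble with columns `time_s`, `index` and `polarity`
#' @method tidy impulse_train
#' @export
tidy.impulse_train <- function(x, ...) {
  tibble::tibble(time_s = x$indices / x$fs_hz, index = x$indices,
                 polarity = x$polarities)
}
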