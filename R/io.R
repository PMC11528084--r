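#' Write an impulse train to a JSON sidecar
#'
#' Plain-text interchange format for stimulus-timing metadata: frequency-
#' agnostic fields `indices`, `polarities`, `rate_per_s`, `duration_s`,
#' `fs_hz`, `seed`. Round-trips exactly.
#'
#' @param train an [impulse_train()]
#' @param path output file path
#' @export
write_impulse_train_json <- function(train, path) {
  stopifnot(inherits(train, "impulse_train"))
  jsonlite::write_json(
    list(indices = train$indices, polarities = train$polarities,
         rate_per_s = train$rate_per_s, duration_s = train$duration_s,
         fs_hz = train$fs_hz, n = train$n, seed = train$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_impulse_train_json
#' @return `read_impulse_train_json()` returns an [impulse_train()]
#' @export
read_impulse_train_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  impulse_train(x$indices %||% integer(0), x$polarities %||% integer(0),
                x$rate_per_s, x$duration_s, x$fs_hz,
                seed = x$seed %||% NA_integer_)
}

#' Write / read an EEG recording as CSV plus JSON sidecar
#'
#' The voltage series goes to a one-column CSV (`sample_v`); sampling rate,
#' trial boundaries and condition metadata go to `<path>.json`. CSV doubles
#' are written with full round-trippable precision, so the round trip is
#' exact.
#'
#' @param eeg an [eeg_recording()]
#' @param path CSV output path
#' @export
write_eeg_csv <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  readr::write_csv(tibble::tibble(sample_v = eeg$samples), path)
  jsonlite::write_json(
    list(fs_hz = eeg$fs_hz, trial_boundaries = eeg$trial_boundaries,
         token_duration_s = eeg$token_duration_s, condition = eeg$condition),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @return `read_eeg_csv()` returns an [eeg_recording()]
#' @export
read_eeg_csv <- function(path) {
  samples <- readr::read_csv(path, show_col_types = FALSE)$sample_v
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_recording(samples, meta$fs_hz, meta$trial_boundaries,
                meta$token_duration_s, condition = as.list(meta$condition))
}
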