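#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a response waveform into a tibble
#'
#' @param x a [response_waveform()]
#' @param ... unused
#' @return a tibble with `lag_ms` and `amplitude_v` (plus condition columns
#'   where available)
#' @method tidy response_waveform
#' @export
tidy.response_waveform <- function(x, ...) {
  out <- tibble::tibble(lag_ms = x$lag_ms, amplitude_v = x$w)
  cond <- x$condition
  for (nm in names(cond))
    if (length(cond[[nm]]) == 1 && !is.null(cond[[nm]]))
      out[[nm]] <- cond[[nm]]
  out
}

#' @rdname tidy.response_waveform
#' @method tidy derived_response
#' @export
tidy.derived_response <- function(x, ...) {
  out <- tidy.response_waveform(x, ...)
  out$band_center_hz <- x$center_hz
  out
}

#' Tidy/glance methods for response-size estimates
#'
#' `tidy()` returns the per-window noise variances; `glance()` returns the
#' one-row summary with `sigma_r_v`, `var_rplusn`, `var_n` and the window
#' bookkeeping.
#'
#' @param x a `response_size_estimate`
#' @param ... unused
#' @method tidy response_size_estimate
#' @export
tidy.response_size_estimate <- function(x, ...) {
  tibble::tibble(window = seq_along(x$noise_window_vars),
                 noise_var = x$noise_window_vars)
}

#' @rdname tidy.response_size_estimate
#' @method glance response_size_estimate
#' @export
glance.response_size_estimate <- function(x, ...) {
  tibble::tibble(sigma_r_v = x$sigma_r, var_rplusn = x$var_rplusn,
                 var_n = x$var_n, window_center_ms = x$window_center_ms,
                 window_len_ms = x$window_len_ms,
                 n_noise_windows = x$n_noise_windows)
}

#' Plot a response waveform
#'
#' @param object a [response_waveform()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot response_waveform
#' @export
autoplot.response_waveform <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_ms, .data$amplitude_v * 1e9)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag re toneburst onset (ms)", y = "Amplitude (nV)") +
    ggplot2::theme_minimal()
}

#' Plot wave V latencies across high-pass-noise cutoff
#'
#' @param results a results tibble from [run_pabr_pipeline()] or
#'   [analyze_condition_cell()]
#' @return a ggplot of latency against cutoff, colored by paradigm and
#'   faceted by rate and test frequency
#' @export
plot_latencies <- function(results) {
  df <- dplyr::filter(results, .data$kind == "masked", !is.na(.data$latency_ms))
  ggplot2::ggplot(df, ggplot2::aes(.data$cutoff_hz, .data$latency_ms,
                                   color = .data$paradigm)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(test_frequency_hz ~ rate_per_s,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "HPN cutoff (Hz)", y = "Wave V latency (ms)") +
    ggplot2::theme_minimal()
}

#' Plot derived-band response sizes
#'
#' @param results a results tibble from [run_pabr_pipeline()] or
#'   [analyze_condition_cell()]
#' @return a ggplot of noise-corrected response size against derived-band
#'   center frequency
#' @export
plot_response_sizes <- function(results) {
  df <- dplyr::filter(results, .data$kind == "derived", !is.na(.data$sigma_r_v))
  ggplot2::ggplot(df, ggplot2::aes(.data$band_center_hz,
                                   .data$sigma_r_v * 1e9,
                                   color = .data$paradigm)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(test_frequency_hz ~ rate_per_s,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Derived band center (Hz)",
                  y = expression(sigma[R] ~ "(nV)")) +
    ggplot2::theme_minimal()
}
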