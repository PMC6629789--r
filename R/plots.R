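#' @importFrom ggplot2 ggplot aes geom_line geom_area facet_wrap labs
#'   autoplot theme_minimal geom_hline
NULL

#' Plot pressure and flow waveforms of a run
#'
#' @param object a `coro_run`.
#' @param vessels vessels to show (default: a representative set).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coro_run <- function(object,
                              vessels = intersect(c("LMCA", "LAD", "LCX", "RCA"),
                                                  names(object$grids)),
                              ...) {
  dat <- purrr::map_dfr(vessels, function(nm) {
    dplyr::mutate(run_series(object, nm, "mid"), vessel = nm)
  })
  long <- tidyr::pivot_longer(dat, c("p", "q"),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, c("p", "q"),
                          c("pressure (mmHg)", "flow (ml/s)"))
  ggplot(long, aes(x = .data$t, y = .data$value, colour = .data$vessel)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a wave decomposition
#'
#' Forward (positive) and backward (negative) wave intensity over the
#' cycle.
#'
#' @param object a `wave_decomposition`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wave_decomposition <- function(object, ...) {
  dat <- tidyr::pivot_longer(as_tibble(object), c("wi_plus", "wi_minus"),
                             names_to = "channel", values_to = "wi")
  ggplot(dat, aes(x = .data$t, y = .data$wi, fill = .data$channel)) +
    geom_area(position = "identity", alpha = 0.6) +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    labs(x = "time (s)", y = "wave intensity (g cm^-1 s^-4)", fill = NULL) +
    theme_minimal()
}

#' Plot an impedance spectrum
#'
#' @param object an `impedance_spectrum`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.impedance_spectrum <- function(object, ...) {
  dat <- tidy.impedance_spectrum(object)
  long <- tidyr::pivot_longer(dat, c("mod_Z", "Re_Z", "Im_Z"),
                              names_to = "part", values_to = "value")
  ggplot(long, aes(x = .data$omega / (2 * pi), y = .data$value)) +
    geom_line() +
    facet_wrap(~part, scales = "free_y", ncol = 1) +
    labs(x = "frequency (Hz)", y = "impedance (g cm^-4 s^-1)") +
    theme_minimal()
}

#' Plot a six-wave energy table
#'
#' @param object a `six_wave_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.six_wave_table <- function(object, ...) {
  dat <- as_tibble(object)
  dat$wave <- factor(dat$wave, letters[1:6])
  ggplot(dat, aes(x = .data$wave, y = .data$percent)) +
    ggplot2::geom_col(aes(fill = .data$type)) +
    labs(x = "wave", y = "% of six-wave energy", fill = NULL) +
    theme_minimal()
}
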