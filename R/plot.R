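# ggplot2 displays for spectra and scans.

#' @export
autoplot.binned_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency_hz, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stick_spectrum <- function(object, window_hz = NULL, npoints = 4000,
                                    broadening_hz = 1, ...) {
  window_hz <- window_hz %||% (2.2 * max(abs(object$frequency_hz)))
  autoplot(bin_spectrum(object, window_hz, npoints, broadening_hz)) +
    ggplot2::labs(
      title = sprintf("%s effective Hamiltonian, wr = %.4g kHz",
                      attr(object, "construction") %||% "",
                      (attr(object, "wr_hz") %||% NA) / 1e3)
    )
}

#' Bin and plot a powder spectrum in one call
#'
#' @param s A `stick_spectrum`.
#' @param ... Passed to [autoplot.stick_spectrum()].
#' @export
plot_spectrum <- function(s, ...) autoplot(s, ...)

#' @export
autoplot.linewidth_scan <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = 1e3 / .data$wr_hz, y = .data$gaussian_fwhm_hz,
                 colour = .data$construction, shape = .data$line)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(1 / nu[r] ~ "(1/kHz)"),
                  y = "Gaussian-equivalent FWHM (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.breadth_scan <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$difference_hz > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wr_hz, y = .data$difference_hz)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spinning frequency (Hz)",
                  y = "breadth difference, order 3 - exact (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shift_scan <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$wr_hz / 1e3, y = .data$deviation_hz,
                 colour = .data$line, linetype = .data$construction)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spinning frequency (kHz)",
                  y = "first-moment deviation from isotropic shift (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decomposition_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wr_hz / 1e3, y = .data$deviation_pct)) +
    ggplot2::geom_col(width = 2) +
    ggplot2::labs(x = "spinning frequency (kHz)",
                  y = "deviation of 3/4-weighted three-spin sum (%)") +
    ggplot2::theme_minimal()
}
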