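#' Plot a recovered optical-property spectrum
#'
#' Facetted wavelength profiles of the recovered absorption, scattering,
#' reduced scattering and anisotropy, with non-converged wavelengths marked.
#'
#' @param object An `ot_spectrum_fit` tibble from [invert_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ot_spectrum_fit <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    dplyr::transmute(df, wavelength_nm = .data$wavelength_nm,
                     quantity = "mu_a (mm^-1)", value = .data$mu_a_mm,
                     converged = .data$converged),
    dplyr::transmute(df, wavelength_nm = .data$wavelength_nm,
                     quantity = "mu_s (mm^-1)", value = .data$mu_s_mm,
                     converged = .data$converged),
    dplyr::transmute(df, wavelength_nm = .data$wavelength_nm,
                     quantity = "mu_s' (mm^-1)", value = .data$mu_s_prime_mm,
                     converged = .data$converged),
    dplyr::transmute(df, wavelength_nm = .data$wavelength_nm,
                     quantity = "g", value = .data$g,
                     converged = .data$converged)
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(data = dplyr::filter(long, !.data$converged),
                        colour = "red", size = 0.6) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ground-truth or replicate spectra by temperature
#'
#' @param spectra Data frame with `wavelength_nm`, `mu_a_mm` and optionally
#'   `temperature` columns (e.g. bound [evaluate_truth()] tables).
#' @param value Column to plot (default `"mu_a_mm"`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, value = "mu_a_mm") {
  stopifnot(value %in% names(spectra))
  p <- ggplot2::ggplot(spectra,
                       ggplot2::aes(.data$wavelength_nm, .data[[value]]))
  if ("temperature" %in% names(spectra)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(colour = .data$temperature,
                   group = interaction(
                     .data$temperature,
                     if ("replicate" %in% names(spectra)) .data$replicate
                     else 1)),
      linewidth = 0.4)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.4)
  }
  p + ggplot2::labs(x = "wavelength (nm)", y = value) +
    ggplot2::theme_minimal()
}
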