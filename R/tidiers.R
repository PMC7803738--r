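#' Tidy a single-wavelength inversion fit
#'
#' @param x An `ot_inversion` object from [invert_optical_properties()].
#' @param ... Unused.
#' @return A tibble with one row per recovered parameter: `term`,
#'   `estimate`, `unit`.
#' @export
tidy.ot_inversion <- function(x, ...) {
  r <- x$recovered
  tibble::tibble(
    term = c("mu_a", "mu_s", "g", "mu_s_prime"),
    estimate = c(r$mu_a, r$mu_s, r$g, r$mu_s_prime),
    unit = c("mm^-1", "mm^-1", "", "mm^-1")
  )
}

#' Glance at a single-wavelength inversion fit
#'
#' @inheritParams tidy.ot_inversion
#' @return A one-row tibble with fit diagnostics: `residual_norm`,
#'   `iterations`, `converged`, `jacobian_refreshes`, `forward_calls`,
#'   `seed`.
#' @export
glance.ot_inversion <- function(x, ...) {
  tibble::tibble(
    residual_norm = x$residual_norm,
    iterations = x$iterations,
    converged = x$converged,
    jacobian_refreshes = x$jacobian_refreshes,
    forward_calls = x$forward_calls,
    seed = x$seed
  )
}

#' Glance at a spectrum fit
#'
#' @param x An `ot_spectrum_fit` tibble from [invert_spectrum()].
#' @param ... Unused.
#' @return A one-row tibble: number of wavelengths, convergence fraction,
#'   median residual and total forward-model calls.
#' @export
glance.ot_spectrum_fit <- function(x, ...) {
  tibble::tibble(
    n_wavelengths = nrow(x),
    n_converged = sum(x$converged, na.rm = TRUE),
    frac_converged = mean(x$converged, na.rm = TRUE),
    median_residual = stats::median(x$residual, na.rm = TRUE),
    total_forward_calls = sum(x$forward_calls, na.rm = TRUE)
  )
}
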