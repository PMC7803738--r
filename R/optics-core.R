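#' Optical properties of a turbid medium
#'
#' Bundle of the per-wavelength unknowns recovered by the inverse algorithm:
#' absorption coefficient, scattering coefficient, Henyey-Greenstein
#' anisotropy factor, plus the refractive index. All coefficients are in
#' mm^-1; set `from_cm = TRUE` to convert inputs given in cm^-1.
#'
#' @param mu_a Absorption coefficient (mm^-1), `>= 0`.
#' @param mu_s Scattering coefficient (mm^-1), `>= 0`.
#' @param g Anisotropy factor (mean scattering cosine), in `(-1, 1)`.
#' @param n Refractive index, `>= 1`.
#' @param from_cm Logical; if `TRUE`, `mu_a` and `mu_s` are interpreted as
#'   cm^-1 and divided by 10.
#' @return An object of class `optical_properties`: a named list with fields
#'   `mu_a`, `mu_s`, `g`, `n` and the derived reduced scattering coefficient
#'   `mu_s_prime = mu_s * (1 - g)`.
#' @examples
#' optical_properties(mu_a = 0.1, mu_s = 10, g = 0.9)
#' @export
optical_properties <- function(mu_a, mu_s, g, n = 1.4, from_cm = FALSE) {
  if (from_cm) {
    mu_a <- mu_a / 10
    mu_s <- mu_s / 10
  }
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g), is.numeric(n))
  if (!all(is.finite(c(mu_a, mu_s, g, n)))) {
    stop("optical properties must be finite", call. = FALSE)
  }
  if (any(mu_a < 0)) stop("mu_a must be >= 0", call. = FALSE)
  if (any(mu_s < 0)) stop("mu_s must be >= 0", call. = FALSE)
  if (any(abs(g) >= 1)) stop("g must lie strictly in (-1, 1)", call. = FALSE)
  if (any(n < 1)) stop("refractive index must be >= 1", call. = FALSE)
  structure(
    list(mu_a = mu_a, mu_s = mu_s, g = g, n = n,
         mu_s_prime = mu_s * (1 - g)),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mu_a = %.4g mm^-1, mu_s = %.4g mm^-1, g = %.4g, n = %.3g (mu_s' = %.4g mm^-1)\n",
    x$mu_a, x$mu_s, x$g, x$n, x$mu_s_prime))
  invisible(x)
}

#' A single slab of the layered sample
#'
#' @param thickness Slab thickness in mm, `> 0`.
#' @param props An [optical_properties()] object.
#' @return An object of class `layer`.
#' @export
layer <- function(thickness, props) {
  stopifnot(inherits(props, "optical_properties"))
  if (!is.numeric(thickness) || length(thickness) != 1 ||
      !is.finite(thickness) || thickness <= 0) {
    stop("layer thickness must be a positive finite scalar (mm)", call. = FALSE)
  }
  structure(list(thickness = thickness, props = props), class = "layer")
}

#' Ordered stack of slabs bounded by an ambient medium
#'
#' In the measurement configuration modelled here the stack is
#' sapphire window / tissue / sapphire window, but any number of layers
#' `>= 1` is accepted.
#'
#' @param layers A list of [layer()] objects, ordered from the illuminated
#'   (top) face downward.
#' @param ambient_n Refractive index of the surrounding medium (air), `>= 1`.
#' @return An object of class `layer_stack`.
#' @seealso [sandwich_stack()] for the window/tissue/window convenience
#'   constructor.
#' @export
layer_stack <- function(layers, ambient_n = 1.0) {
  if (inherits(layers, "layer")) layers <- list(layers)
  stopifnot(is.list(layers), length(layers) >= 1)
  ok <- vapply(layers, inherits, logical(1), what = "layer")
  if (!all(ok)) stop("all elements of `layers` must be layer() objects", call. = FALSE)
  if (!is.numeric(ambient_n) || ambient_n < 1) {
    stop("ambient_n must be >= 1", call. = FALSE)
  }
  structure(list(layers = layers, ambient_n = ambient_n), class = "layer_stack")
}

#' Sapphire/tissue/sapphire sandwich stack
#'
#' Convenience constructor for the three-layer sample geometry: a tissue slab
#' clamped between two clear (non-scattering, non-absorbing) sapphire
#' windows.
#'
#' @param tissue An [optical_properties()] object for the tissue layer.
#' @param tissue_thickness Tissue thickness in mm (default 0.3, mouse-ear
#'   scale).
#' @param window_n Refractive index of the windows (default 1.76, sapphire;
#'   dispersion neglected).
#' @param window_thickness Window thickness in mm (default 1.0 each).
#' @param ambient_n Refractive index of the surroundings (default 1, air).
#' @return A three-layer [layer_stack()].
#' @export
sandwich_stack <- function(tissue, tissue_thickness = 0.3,
                           window_n = 1.76, window_thickness = 1.0,
                           ambient_n = 1.0) {
  clear <- optical_properties(0, 0, 0, n = window_n)
  layer_stack(
    list(
      layer(window_thickness, clear),
      layer(tissue_thickness, tissue),
      layer(window_thickness, clear)
    ),
    ambient_n = ambient_n
  )
}

# internal: unpack a stack into parallel vectors for the C++ kernel
stack_arrays <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  list(
    thickness = vapply(stack$layers, function(l) l$thickness, numeric(1)),
    mu_a = vapply(stack$layers, function(l) l$props$mu_a, numeric(1)),
    mu_s = vapply(stack$layers, function(l) l$props$mu_s, numeric(1)),
    g = vapply(stack$layers, function(l) l$props$g, numeric(1)),
    n = vapply(stack$layers, function(l) l$props$n, numeric(1)),
    ambient_n = stack$ambient_n
  )
}

# internal: index of the (single) scattering/absorbing layer, used by the
# inverse solver to substitute trial tissue properties
tissue_layer_index <- function(stack) {
  arr <- stack_arrays(stack)
  turbid <- which(arr$mu_a + arr$mu_s > 0)
  if (length(turbid) == 0) {
    # all-clear stack: take the middle layer by convention
    return(ceiling(length(stack$layers) / 2))
  }
  if (length(turbid) > 1) {
    stop("the inverse solver supports exactly one turbid (tissue) layer",
         call. = FALSE)
  }
  turbid
}

#' Sample the Henyey-Greenstein deflection cosine
#'
#' Deterministic inverse-CDF transform of a uniform deviate into a scattering
#' angle cosine distributed per the Henyey-Greenstein phase function
#' \eqn{p(\cos\theta) = (1-g^2) / (2 (1 + g^2 - 2 g \cos\theta)^{3/2})}.
#' For `g = 0` this reduces to the isotropic `2 u - 1`.
#'
#' @param g Anisotropy factor, strictly inside `(-1, 1)`.
#' @param u Uniform deviates in `[0, 1)`; vectorized.
#' @return Deflection cosines in `[-1, 1]`, same length as `u`.
#' @examples
#' sample_hg_cosine(0, 0.75)        # isotropic limit: 0.5
#' mean(sample_hg_cosine(0.9, runif(1e5)))  # ~ 0.9
#' @export
sample_hg_cosine <- function(g, u) {
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || abs(g) >= 1) {
    stop("g must be a scalar strictly inside (-1, 1)", call. = FALSE)
  }
  stopifnot(all(u >= 0), all(u < 1))
  if (abs(g) < 1e-12) {
    return(2 * u - 1)
  }
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - t^2) / (2 * g)))
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized Fresnel reflection coefficients, with
#' the refracted-angle cosine from Snell's law. Under total internal
#' reflection the reflectance is exactly 1 and `cos_transmitted` is `NA`.
#'
#' @param n_in Refractive index of the incidence medium, `>= 1`.
#' @param n_out Refractive index of the transmission medium, `>= 1`.
#' @param cos_incident Cosine of the incidence angle, in `[0, 1]`; vectorized.
#' @return A [tibble::tibble()] with columns `reflectance` and
#'   `cos_transmitted`.
#' @examples
#' fresnel_reflectance(1.0, 1.76, 1.0)  # normal incidence on sapphire
#' @export
fresnel_reflectance <- function(n_in, n_out, cos_incident) {
  if (any(n_in < 1) || any(n_out < 1)) {
    stop("refractive indices must be >= 1", call. = FALSE)
  }
  if (any(cos_incident < 0) || any(cos_incident > 1)) {
    stop("cos_incident must lie in [0, 1]", call. = FALSE)
  }
  k <- pmax(length(n_in), length(n_out), length(cos_incident))
  n1 <- rep_len(n_in, k); n2 <- rep_len(n_out, k)
  ci <- rep_len(cos_incident, k)
  st2 <- (n1 / n2)^2 * (1 - ci^2)
  tir <- st2 >= 1
  ct <- ifelse(tir, NA_real_, sqrt(pmax(0, 1 - st2)))
  rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
  rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
  refl <- ifelse(tir, 1, 0.5 * (rs^2 + rp^2))
  tibble::tibble(reflectance = refl, cos_transmitted = ct)
}
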