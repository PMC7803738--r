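#' Integrating-sphere collection geometry
#'
#' Fixed parameters of the measurement arrangement: a 1.9 mm collimated beam
#' focused on the sample at a 5 mm sphere port, a 25.4 mm reference-side
#' entrance port, a lateral extent beyond which photon weight is counted as
#' edge loss, and the acceptance half-angle below which forward-exiting light
#' is treated as unscattered (collimated).
#'
#' @param beam_diameter Beam diameter at the sample, mm.
#' @param sample_port_diameter Diameter of the transmittance entrance /
#'   reflectance exit port, mm.
#' @param reference_port_diameter Diameter of the reflectance-side entrance
#'   port, mm.
#' @param lateral_extent Radius (mm) beyond which photons are terminated and
#'   scored as edge losses (the scale of the ear beyond the port).
#' @param collimation_half_angle Acceptance half-angle (degrees) defining the
#'   unscattered exit cone.
#' @return An object of class `sphere_geometry`.
#' @export
sphere_geometry <- function(beam_diameter = 1.9,
                            sample_port_diameter = 5.0,
                            reference_port_diameter = 25.4,
                            lateral_extent = 6.0,
                            collimation_half_angle = 2.5) {
  vals <- c(beam_diameter, sample_port_diameter, reference_port_diameter,
            lateral_extent, collimation_half_angle)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be positive and finite", call. = FALSE)
  }
  if (beam_diameter > sample_port_diameter) {
    stop("beam_diameter must not exceed sample_port_diameter", call. = FALSE)
  }
  if (collimation_half_angle >= 90) {
    stop("collimation_half_angle must be < 90 degrees", call. = FALSE)
  }
  structure(
    list(beam_diameter = beam_diameter,
         sample_port_diameter = sample_port_diameter,
         reference_port_diameter = reference_port_diameter,
         lateral_extent = lateral_extent,
         collimation_half_angle = collimation_half_angle),
    class = "sphere_geometry"
  )
}

#' Monte Carlo simulation configuration
#'
#' @param n_photons Number of photon packets to launch, `>= 1`.
#' @param seed Integer seed of the simulation's private RNG stream; the same
#'   (stack, geometry, config) including seed reproduces results bit for bit.
#' @param roulette_threshold Packet weight below which Russian roulette is
#'   played, in `(0, 1)`.
#' @param roulette_survival Roulette survival probability, in `(0, 1]`.
#' @param include_specular_in_Rd If `TRUE`, the specularly reflected fraction
#'   is folded into `Rd` (sensitivity checks only; the reflectance reference
#'   in the modelled instrument is a diffuse standard, so the default
#'   excludes it).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_photons = 2e4, seed = 1L,
                       roulette_threshold = 1e-4,
                       roulette_survival = 0.1,
                       include_specular_in_Rd = FALSE) {
  if (!is.finite(n_photons) || n_photons < 1) {
    stop("n_photons must be >= 1", call. = FALSE)
  }
  if (roulette_threshold <= 0 || roulette_threshold >= 1) {
    stop("roulette_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (roulette_survival <= 0 || roulette_survival > 1) {
    stop("roulette_survival must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_photons = as.integer(round(n_photons)), seed = as.integer(seed),
         roulette_threshold = roulette_threshold,
         roulette_survival = roulette_survival,
         include_specular_in_Rd = isTRUE(include_specular_in_Rd)),
    class = "sim_config"
  )
}

#' Simulate the integrating-sphere observables for a layered sample
#'
#' Launches photon packets normally onto the stack, uniformly over the beam
#' disc, and propagates them with free paths `s = -ln(xi) / (mu_a + mu_s)`,
#' weight-decrement absorption, Henyey-Greenstein scattering, Fresnel
#' decisions at every interface, Russian roulette termination, and lateral
#' edge-loss accounting. The never-scattered axial (ballistic) cascade is
#' evaluated analytically by weight splitting, which makes the collimated
#' transmittance `Tc` a zero-variance (deterministic) tally; the weight
#' interacting in the tissue spawns random walkers at forced-interaction
#' depths. Exiting weight is tallied as diffuse reflectance `Rd` (backward,
#' within the sample port, order-0 specular excluded), total transmittance
#' `Tt` (forward, within the port, ballistic included) and diffuse
#' transmittance `Td = Tt - Tc` (scattered forward transmittance).
#'
#' @param stack A [layer_stack()] (or [sandwich_stack()]).
#' @param geom A [sphere_geometry()].
#' @param cfg A [sim_config()].
#' @return A one-row [tibble::tibble()] with columns `Rd`, `Tt`, `Td`, `Tc`,
#'   `absorbed`, `edge_loss`, `specular`, `unscored`, `se_Rd`, `se_Tt`,
#'   `se_Td`, `n_photons`, `seed`. All fractions are per unit incident power;
#'   the scored channels `Rd + Tt + absorbed + edge_loss + specular +
#'   unscored` sum to 1 to within floating-point bookkeeping (~1e-13).
#' @examples
#' st <- sandwich_stack(optical_properties(0.1, 10, 0.9))
#' simulate_measurements(st, sphere_geometry(), sim_config(5e3, seed = 7))
#' @export
simulate_measurements <- function(stack, geom = sphere_geometry(),
                                  cfg = sim_config()) {
  stopifnot(inherits(stack, "layer_stack"), inherits(geom, "sphere_geometry"),
            inherits(cfg, "sim_config"))
  arr <- stack_arrays(stack)
  if (!all(is.finite(c(arr$mu_a, arr$mu_s, arr$g, arr$n, arr$thickness)))) {
    stop("non-finite optical properties in stack", call. = FALSE)
  }
  if (geom$beam_diameter <= 0) stop("zero-area beam", call. = FALSE)

  res <- mc_forward_cpp(
    thickness = arr$thickness, mu_a = arr$mu_a, mu_s = arr$mu_s,
    g = arr$g, n_layer = arr$n, n_ambient = arr$ambient_n,
    beam_radius = geom$beam_diameter / 2,
    port_radius = geom$sample_port_diameter / 2,
    lateral_extent = geom$lateral_extent,
    cos_collim = cos(geom$collimation_half_angle * pi / 180),
    n_photons = cfg$n_photons,
    seed = cfg$seed,
    roulette_threshold = cfg$roulette_threshold,
    roulette_survival = cfg$roulette_survival
  )

  Rd <- res$Rd
  specular <- res$specular
  if (cfg$include_specular_in_Rd) {
    Rd <- Rd + specular
    specular <- 0
  }
  tibble::tibble(
    Rd = Rd, Tt = res$Tt, Td = res$Td, Tc = res$Tc,
    absorbed = res$absorbed, edge_loss = res$edge_loss,
    specular = specular, unscored = res$unscored,
    se_Rd = res$se_Rd, se_Tt = res$se_Tt, se_Td = res$se_Td,
    n_photons = cfg$n_photons, seed = cfg$seed
  )
}

#' Collimated transmittance from total and diffuse transmittance
#'
#' `Tc = max(Tt - Td, 0)`, with negative differences below the noise floor
#' silently clipped to zero and larger negative differences flagged.
#'
#' @param Tt Total transmittance fraction(s) in `[0, 1]`.
#' @param Td Diffuse transmittance fraction(s) in `[0, 1]`.
#' @param noise_floor Magnitude of negative `Tt - Td` tolerated as
#'   measurement noise before the `clipped` flag is raised.
#' @return A [tibble::tibble()] with columns `Tc` and `clipped`.
#' @examples
#' collimated_from_total_diffuse(0.50, 0.45)
#' @export
collimated_from_total_diffuse <- function(Tt, Td, noise_floor = 1e-3) {
  if (any(Tt < 0 | Tt > 1 | Td < 0 | Td > 1, na.rm = TRUE)) {
    stop("transmittance fractions must lie in [0, 1]", call. = FALSE)
  }
  d <- Tt - Td
  tibble::tibble(Tc = pmax(d, 0), clipped = d < -noise_floor)
}
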