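#' Gaussian chromophore absorption band
#'
#' @param center Band center, nm (within 380-1700).
#' @param width Gaussian sigma, nm, `> 0`.
#' @param amplitude Peak absorption contribution, mm^-1, `>= 0`.
#' @return An object of class `chromophore_band`.
#' @export
chromophore_band <- function(center, width, amplitude) {
  if (center < 380 || center > 1700) {
    stop("band center must lie within 380-1700 nm", call. = FALSE)
  }
  if (width <= 0) stop("band width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("band amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "chromophore_band")
}

band_sum <- function(bands, wl) {
  if (length(bands) == 0) return(rep(0, length(wl)))
  Reduce(`+`, lapply(bands, function(b) {
    b$amplitude * exp(-(wl - b$center)^2 / (2 * b$width^2))
  }))
}

#' Parametric tissue spectrum model
#'
#' Ground-truth generator for mouse-ear-like optical-property spectra:
#' absorption is a flat baseline plus Gaussian chromophore bands
#' (oxy-/deoxy-hemoglobin mixed by the oxygen saturation, plus water bands),
#' scattering follows a power law `mu_s = a (lambda/lambda_ref)^(-b)`, and
#' the anisotropy factor follows a clipped linear trend.
#'
#' @param hemoglobin_bands_oxy,hemoglobin_bands_deoxy,water_bands Lists of
#'   [chromophore_band()] objects.
#' @param oxygen_saturation Fraction of hemoglobin in the oxygenated state,
#'   in `[0, 1]`.
#' @param blood_amplitude_scale,water_amplitude_scale Dimensionless scale
#'   factors on the hemoglobin and water band amplitudes (tissue shrinkage
#'   concentrates chromophores, so the heated preset uses values > 1).
#' @param scatter_a Scattering coefficient (mm^-1) at `lambda_ref`.
#' @param scatter_b Power-law exponent of the scattering decay.
#' @param lambda_ref Reference wavelength for the scattering law, nm.
#' @param g0 Anisotropy factor at `lambda_ref`.
#' @param g_slope Anisotropy trend per nm.
#' @param baseline_mu_a Flat absorption background, mm^-1.
#' @param n Tissue refractive index.
#' @return An object of class `tissue_spectrum_model`.
#' @export
tissue_spectrum_model <- function(hemoglobin_bands_oxy = list(),
                                  hemoglobin_bands_deoxy = list(),
                                  water_bands = list(),
                                  oxygen_saturation = 0.9,
                                  blood_amplitude_scale = 1,
                                  water_amplitude_scale = 1,
                                  scatter_a = 18, scatter_b = 1.2,
                                  lambda_ref = 500,
                                  g0 = 0.92, g_slope = 2.5e-5,
                                  baseline_mu_a = 0.08, n = 1.4) {
  stopifnot(oxygen_saturation >= 0, oxygen_saturation <= 1,
            scatter_a > 0, baseline_mu_a >= 0, n >= 1)
  structure(
    list(hemoglobin_bands_oxy = hemoglobin_bands_oxy,
         hemoglobin_bands_deoxy = hemoglobin_bands_deoxy,
         water_bands = water_bands,
         oxygen_saturation = oxygen_saturation,
         blood_amplitude_scale = blood_amplitude_scale,
         water_amplitude_scale = water_amplitude_scale,
         scatter_a = scatter_a, scatter_b = scatter_b,
         lambda_ref = lambda_ref, g0 = g0, g_slope = g_slope,
         baseline_mu_a = baseline_mu_a, n = n),
    class = "tissue_spectrum_model"
  )
}

#' Temperature presets for the synthetic mouse-ear spectra
#'
#' Shipped ground-truth models for the three temperature conditions. Band
#' centers are placed at the printed peak positions for each condition
#' (Soret 417 nm at 25/36 C vs 426 nm at 60 C; oxyhemoglobin doublet
#' 545/575 nm at the lower temperatures replaced by a single 557 nm
#' deoxyhemoglobin band plus a 905 nm band at 60 C; water bands
#' 1192/1454 nm at 25 C, 1192/1449 nm at 36 C, blue-shifted to
#' 1184/1441 nm at 60 C). The heated preset has near-zero oxygen
#' saturation, larger band amplitude scales (chromophore concentration by
#' shrinkage), a steeper scattering power law and a lower baseline
#' anisotropy. Band widths and amplitudes are model choices, not literature
#' values.
#'
#' @param label One of `"25C"`, `"36C"`, `"60C"`.
#' @return An object of class `temperature_preset`: a list with fields
#'   `label` and `model` (a [tissue_spectrum_model()]).
#' @examples
#' evaluate_truth(temperature_preset("60C"), seq(1350, 1550, 2))
#' @export
temperature_preset <- function(label = c("25C", "36C", "60C")) {
  label <- match.arg(label)

  oxy <- list(
    chromophore_band(417, 15, 3.00),   # Soret, oxygenated
    chromophore_band(545, 10, 0.35),   # beta band
    chromophore_band(575, 10, 0.36)    # alpha band
  )
  deoxy <- list(
    chromophore_band(426, 15, 3.20),   # Soret, deoxygenated
    chromophore_band(557, 10, 0.55),
    chromophore_band(905, 30, 0.10)
  )
  water <- function(c1, c2) list(
    chromophore_band(c1, 35, 0.35),
    chromophore_band(c2, 45, 1.00)
  )

  model <- switch(label,
    "25C" = tissue_spectrum_model(
      hemoglobin_bands_oxy = oxy, hemoglobin_bands_deoxy = deoxy,
      water_bands = water(1192, 1454),
      oxygen_saturation = 0.93,
      blood_amplitude_scale = 1, water_amplitude_scale = 1,
      scatter_a = 18, scatter_b = 1.20, g0 = 0.920, g_slope = 2.5e-5,
      baseline_mu_a = 0.09
    ),
    "36C" = tissue_spectrum_model(
      hemoglobin_bands_oxy = oxy, hemoglobin_bands_deoxy = deoxy,
      water_bands = water(1192, 1449),
      oxygen_saturation = 0.90,
      blood_amplitude_scale = 1, water_amplitude_scale = 1,
      scatter_a = 18.5, scatter_b = 1.25, g0 = 0.918, g_slope = 2.5e-5,
      baseline_mu_a = 0.09
    ),
    "60C" = tissue_spectrum_model(
      hemoglobin_bands_oxy = oxy, hemoglobin_bands_deoxy = deoxy,
      water_bands = water(1184, 1441),
      oxygen_saturation = 0.03,
      blood_amplitude_scale = 1.5, water_amplitude_scale = 1.3,
      scatter_a = 26, scatter_b = 1.55, g0 = 0.885, g_slope = 2.0e-5,
      baseline_mu_a = 0.10
    )
  )
  structure(list(label = label, model = model), class = "temperature_preset")
}

#' Evaluate the ground-truth optical properties of a preset on a grid
#'
#' @param preset A [temperature_preset()] (or bare
#'   [tissue_spectrum_model()]).
#' @param wavelengths Strictly increasing wavelength grid, nm, within
#'   380-1700.
#' @return A [tibble::tibble()] with columns `wavelength_nm`, `mu_a_mm`,
#'   `mu_s_mm`, `g`, `mu_s_prime_mm`, `n`.
#' @export
evaluate_truth <- function(preset, wavelengths) {
  model <- if (inherits(preset, "temperature_preset")) preset$model else preset
  stopifnot(inherits(model, "tissue_spectrum_model"))
  wl <- as.numeric(wavelengths)
  if (any(wl < 380 | wl > 1700)) {
    stop("wavelength grid must lie within 380-1700 nm", call. = FALSE)
  }
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  s <- model$oxygen_saturation
  mu_a <- model$baseline_mu_a +
    model$blood_amplitude_scale *
      (s * band_sum(model$hemoglobin_bands_oxy, wl) +
       (1 - s) * band_sum(model$hemoglobin_bands_deoxy, wl)) +
    model$water_amplitude_scale * band_sum(model$water_bands, wl)
  mu_s <- model$scatter_a * (wl / model$lambda_ref)^(-model$scatter_b)
  g <- pmin(0.999, pmax(1e-3, model$g0 + model$g_slope * (wl - model$lambda_ref)))
  tibble::tibble(
    wavelength_nm = wl, mu_a_mm = mu_a, mu_s_mm = mu_s, g = g,
    mu_s_prime_mm = mu_s * (1 - g), n = model$n
  )
}

# Deterministic seed fan-out: one master seed -> independent 31-bit child
# seeds per (stream, index) via a splitmix-style integer hash.
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master) %% 2^31
  for (k in c(idx, 1)) {
    x <- (x * 69069 + as.double(k) * 2654435761 + 1013904223) %% 2^31
    x <- ((x * 1103515245) + 12345) %% 2^31
  }
  as.integer(x %% (2^31 - 1)) + 1L
}

#' Generate a noisy synthetic measurement set from a preset
#'
#' Evaluates the preset's ground truth on the grid, forward-simulates each
#' wavelength through the sandwich stack with an independent per-wavelength
#' RNG stream, then applies independent multiplicative Gaussian measurement
#' noise `(1 + eps)`, `eps ~ N(0, noise_cv^2)`, to `Rd`, `Tt`, `Td`, clips
#' to `[0, 1]`, restores `Td <= Tt`, and recomputes `Tc = Tt - Td`.
#'
#' @param preset A [temperature_preset()].
#' @param wavelengths Strictly increasing grid, nm.
#' @param geom A [sphere_geometry()].
#' @param stack_template A [layer_stack()] whose turbid layer is replaced by
#'   the preset truth at each wavelength; defaults to the standard
#'   sandwich.
#' @param cfg A [sim_config()]; its seed field is ignored in favour of
#'   per-wavelength seeds derived from `seed`.
#' @param noise_cv Relative SD of the multiplicative measurement noise.
#' @param seed Master seed; `(preset, seed)` fully determines the output.
#' @param replicate Replicate index mixed into the seed fan-out.
#' @return A list with elements `measurements` (tibble: `wavelength_nm`,
#'   `Rd`, `Tt`, `Td`, `Tc`, `se_Rd`, `se_Tt`, `se_Td`, `n_photons`, `seed`)
#'   and `truth` (the [evaluate_truth()] table). Truth never leaks into the
#'   measurement table.
#' @export
generate_measurement_set <- function(preset, wavelengths,
                                     geom = sphere_geometry(),
                                     stack_template = NULL,
                                     cfg = sim_config(),
                                     noise_cv = 0.01,
                                     seed = 1L,
                                     replicate = 1L) {
  stopifnot(inherits(preset, "temperature_preset"), noise_cv >= 0)
  truth <- evaluate_truth(preset, wavelengths)
  if (is.null(stack_template)) {
    stack_template <- sandwich_stack(
      optical_properties(0.1, 10, 0.9, n = preset$model$n))
  }
  ti <- tissue_layer_index(stack_template)

  rows <- purrr::pmap(
    list(truth$wavelength_nm, truth$mu_a_mm, truth$mu_s_mm, truth$g,
         seq_along(truth$wavelength_nm)),
    function(wl, mua, mus, gg, i) {
      st <- stack_template
      st$layers[[ti]] <- layer(
        st$layers[[ti]]$thickness,
        optical_properties(mua, mus, gg, n = st$layers[[ti]]$props$n))
      wl_seed <- derive_seed(seed, replicate, i)
      cfg_i <- cfg
      cfg_i$seed <- wl_seed
      m <- simulate_measurements(st, geom, cfg_i)
      m$wavelength_nm <- wl
      m
    }
  )
  meas <- dplyr::bind_rows(rows)

  # multiplicative noise under a local, restorable RNG state
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(derive_seed(seed, replicate, 0L, 7919L))
    nw <- nrow(meas)
    meas$Rd <- pmin(1, pmax(0, meas$Rd * (1 + stats::rnorm(nw, 0, noise_cv))))
    meas$Tt <- pmin(1, pmax(0, meas$Tt * (1 + stats::rnorm(nw, 0, noise_cv))))
    meas$Td <- pmin(1, pmax(0, meas$Td * (1 + stats::rnorm(nw, 0, noise_cv))))
    meas$Td <- pmin(meas$Td, meas$Tt)
  }
  meas$Tc <- pmax(meas$Tt - meas$Td, 0)

  meas <- dplyr::select(
    meas, "wavelength_nm", "Rd", "Tt", "Td", "Tc",
    "se_Rd", "se_Tt", "se_Td", "n_photons", "seed")
  list(measurements = meas, truth = truth)
}

#' Generate replicate truth-level spectra with measurement-like noise
#'
#' Lightweight replicate generator for the statistical-analysis stage:
#' evaluates the preset truth and applies independent multiplicative
#' Gaussian noise per replicate and wavelength to the property columns.
#' Emulates across-animal variability of recovered spectra without the cost
#' of a full forward-and-invert cycle per replicate.
#'
#' @inheritParams generate_measurement_set
#' @param n_replicates Number of replicate spectra.
#' @return A tibble with columns `replicate`, `wavelength_nm`, `mu_a_mm`,
#'   `mu_s_mm`, `g`, `mu_s_prime_mm`.
#' @export
generate_replicate_spectra <- function(preset, wavelengths, n_replicates,
                                       noise_cv = 0.01, seed = 1L) {
  stopifnot(inherits(preset, "temperature_preset"), n_replicates >= 1,
            noise_cv >= 0)
  truth <- evaluate_truth(preset, wavelengths)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    set.seed(derive_seed(seed, r, 104729L))
    nw <- nrow(truth)
    mu_a <- truth$mu_a_mm * (1 + stats::rnorm(nw, 0, noise_cv))
    mu_s <- truth$mu_s_mm * (1 + stats::rnorm(nw, 0, noise_cv))
    g <- pmin(0.999, pmax(0, truth$g * (1 + stats::rnorm(nw, 0, noise_cv))))
    tibble::tibble(
      replicate = r, wavelength_nm = truth$wavelength_nm,
      mu_a_mm = pmax(0, mu_a), mu_s_mm = pmax(0, mu_s), g = g,
      mu_s_prime_mm = pmax(0, mu_s) * (1 - g))
  })
}

#' Serialize / restore a tissue spectrum model as YAML
#'
#' @param preset A [temperature_preset()].
#' @param path File path to write to.
#' @return `write_preset_yaml` returns `path` invisibly; `read_preset_yaml`
#'   returns a [temperature_preset()].
#' @export
write_preset_yaml <- function(preset, path) {
  stopifnot(inherits(preset, "temperature_preset"))
  m <- preset$model
  to_list <- function(bands) lapply(bands, function(b) {
    list(center = b$center, width = b$width, amplitude = b$amplitude)
  })
  obj <- list(
    label = preset$label,
    model = list(
      hemoglobin_bands_oxy = to_list(m$hemoglobin_bands_oxy),
      hemoglobin_bands_deoxy = to_list(m$hemoglobin_bands_deoxy),
      water_bands = to_list(m$water_bands),
      oxygen_saturation = m$oxygen_saturation,
      blood_amplitude_scale = m$blood_amplitude_scale,
      water_amplitude_scale = m$water_amplitude_scale,
      scatter_a = m$scatter_a, scatter_b = m$scatter_b,
      lambda_ref = m$lambda_ref, g0 = m$g0, g_slope = m$g_slope,
      baseline_mu_a = m$baseline_mu_a, n = m$n
    )
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_preset_yaml
#' @param path File path to read from.
#' @export
read_preset_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  from_list <- function(lst) lapply(lst, function(b) {
    chromophore_band(b$center, b$width, b$amplitude)
  })
  m <- obj$model
  model <- tissue_spectrum_model(
    hemoglobin_bands_oxy = from_list(m$hemoglobin_bands_oxy),
    hemoglobin_bands_deoxy = from_list(m$hemoglobin_bands_deoxy),
    water_bands = from_list(m$water_bands),
    oxygen_saturation = m$oxygen_saturation,
    blood_amplitude_scale = m$blood_amplitude_scale,
    water_amplitude_scale = m$water_amplitude_scale,
    scatter_a = m$scatter_a, scatter_b = m$scatter_b,
    lambda_ref = m$lambda_ref, g0 = m$g0, g_slope = m$g_slope,
    baseline_mu_a = m$baseline_mu_a, n = m$n
  )
  structure(list(label = obj$label, model = model),
            class = "temperature_preset")
}
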