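geom <- sphere_geometry()

test_that("initial guess recovers the attenuation scale from Tc", {
  # Beer-Lambert inversion of the generated Tc: mu_a + mu_s within a factor
  # of 3 of the true mu_t = 10.1 mm^-1
  st <- sandwich_stack(optical_properties(0.1, 10, 0.9))
  meas <- simulate_measurements(st, geom, sim_config(5e4, seed = 31))
  cfg <- inversion_config(seed = 31L)
  ig <- initial_guess(meas, st, geom, cfg)
  mu_t_hat <- ig$mu_a + ig$mu_s
  expect_gt(mu_t_hat, 10.1 / 3)
  expect_lt(mu_t_hat, 10.1 * 3)

  # clear absorber: mu_t estimate is Beer-Lambert-exact up to the grid
  st2 <- layer_stack(list(
    layer(1, optical_properties(0, 0, 0, n = 1)),
    layer(0.3, optical_properties(1, 0, 0, n = 1)),
    layer(1, optical_properties(0, 0, 0, n = 1))), ambient_n = 1)
  meas2 <- simulate_measurements(st2, geom, sim_config(2e4, seed = 32))
  ig2 <- initial_guess(meas2, st2, geom, inversion_config(seed = 32L))
  expect_gt(ig2$mu_a + ig2$mu_s, 0.5)
  expect_lt(ig2$mu_a + ig2$mu_s, 2.0)
})

test_that("zero collimated signal falls back to a bounds-interior grid search", {
  st <- sandwich_stack(optical_properties(0.1, 10, 0.9))
  cfg <- inversion_config(seed = 33L)
  ig <- initial_guess(list(Rd = 0.05, Tt = 0.01, Tc = 0), st, geom, cfg)
  b <- cfg$bounds
  expect_gte(ig$mu_a, b$mu_a[1]); expect_lte(ig$mu_a, b$mu_a[2])
  expect_gte(ig$mu_s, b$mu_s[1]); expect_lte(ig$mu_s, b$mu_s[2])
  expect_gt(ig$g, b$g[1]); expect_lt(ig$g, b$g[2])
})

test_that("a measurement equal to the model at the start is a fixed point", {
  st <- sandwich_stack(optical_properties(0.2, 8, 0.88))
  cfg <- inversion_config(seed = 44L, n_photons_inversion = 1e4)
  meas <- simulate_measurements(st, geom, sim_config(1e4, seed = 44))
  fit <- invert_optical_properties(meas, st, geom, cfg,
                                   start = optical_properties(0.2, 8, 0.88))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 1)
  expect_lt(fit$residual_norm, 1e-9)
})

test_that("a single-wavelength round trip recovers the generating truth", {
  truth <- optical_properties(0.05, 5, 0.90)
  st <- sandwich_stack(truth)
  meas <- simulate_measurements(st, geom, sim_config(2e4, seed = 55))
  cfg <- inversion_config(seed = 55L, n_photons_inversion = 2e4,
                          residual_tolerance = 1e-6)
  fit <- invert_optical_properties(meas, st, geom, cfg)
  r <- fit$recovered
  # mu_a at mu_a*d = 0.015 sits near the common-random-numbers smoothness
  # floor; 10% is what the estimator supports there (mu_s and g are pinned
  # far more tightly by the collimated channel)
  expect_lt(abs(r$mu_a - 0.05) / 0.05, 0.10)
  expect_lt(abs(r$mu_s - 5) / 5, 0.05)
  expect_lt(abs(r$g - 0.90), 0.02)
  # reproducibility: the whole inversion is deterministic given the seed
  fit2 <- invert_optical_properties(meas, st, geom, cfg)
  expect_identical(tidy(fit), tidy(fit2))
  expect_identical(glance(fit), glance(fit2))
})

test_that("forward-call budget respects the Broyden economy", {
  # finite differences only at init/refresh: calls bounded by
  # 1 (residual at start) + 3 per refresh + 1 per iteration
  st <- sandwich_stack(optical_properties(0.1, 10, 0.9))
  meas <- simulate_measurements(st, geom, sim_config(2e4, seed = 66))
  cfg <- inversion_config(seed = 66L)
  fit <- invert_optical_properties(meas, st, geom, cfg)
  expect_lte(fit$forward_calls,
             1 + fit$iterations + 3 * (fit$jacobian_refreshes + 1))
})

test_that("noise propagation: scattering and anisotropy stay accurate", {
  # 1% multiplicative measurement noise at truth (0.03, 8, 0.92); the
  # collimated channel pins mu_t so mu_s and g recover to ~1%; mu_a at
  # mu_a*d ~ 0.01 is noise-limited (its absorption signal is the same
  # order as the injected noise) and only loosely bounded
  truth <- c(0.03, 8, 0.92)
  st <- sandwich_stack(optical_properties(truth[1], truth[2], truth[3]))
  errs <- vapply(1:8, function(k) {
    seed <- 700 + k
    meas <- simulate_measurements(st, geom, sim_config(2e4, seed = seed))
    set.seed(seed)
    noisy <- list(Rd = meas$Rd * (1 + rnorm(1, 0, 0.01)),
                  Tt = meas$Tt * (1 + rnorm(1, 0, 0.01)),
                  Tc = meas$Tc * (1 + rnorm(1, 0, 0.01)))
    fit <- invert_optical_properties(noisy, st, geom,
                                     inversion_config(seed = seed))
    r <- fit$recovered
    c(abs(r$mu_a - truth[1]) / truth[1],
      abs(r$mu_s - truth[2]) / truth[2],
      abs(r$g - truth[3]))
  }, numeric(3))
  expect_lte(median(errs[2, ]), 0.10)   # mu_s within 10 %
  expect_lte(median(errs[3, ]), 0.01)   # g within 0.01
  expect_lte(median(errs[1, ]), 0.80)   # mu_a: noise-limited regime
})

test_that("non-convergence is reported through the flag, never an error", {
  st <- sandwich_stack(optical_properties(0.1, 10, 0.9))
  meas <- simulate_measurements(st, geom, sim_config(2e4, seed = 88))
  cfg <- inversion_config(seed = 89L, max_iterations = 1,
                          residual_tolerance = 1e-14)
  fit <- invert_optical_properties(meas, st, geom, cfg)
  expect_s3_class(fit, "ot_inversion")
  expect_false(fit$converged)
  expect_true(is.finite(fit$residual_norm))
})

test_that("physically unattainable measurements raise an invalid-measurement error", {
  st <- sandwich_stack(optical_properties(0.1, 10, 0.9))
  expect_error(
    invert_optical_properties(list(Rd = 0.7, Tt = 0.6, Tc = 0.1), st, geom),
    "Rd \\+ Tt")
  expect_error(
    invert_optical_properties(list(Rd = -0.1, Tt = 0.6, Tc = 0.1), st, geom),
    "\\[0, 1\\]")
})

test_that("spectrum inversion reduces to the single-point fit on one row", {
  truth <- optical_properties(0.2, 12, 0.9)
  st <- sandwich_stack(truth)
  meas <- simulate_measurements(st, geom, sim_config(2e4, seed = 91))
  meas$wavelength_nm <- 800
  cfg <- inversion_config(seed = 91L)
  single <- invert_optical_properties(meas, st, geom, cfg)
  spec <- invert_spectrum(meas, st, geom, cfg)
  expect_equal(spec$mu_a_mm, single$recovered$mu_a)
  expect_equal(spec$mu_s_mm, single$recovered$mu_s)
  expect_equal(spec$g, single$recovered$g)
  expect_equal(spec$residual, single$residual_norm)
})

test_that("a corrupted row is flagged without contaminating its neighbours", {
  preset <- temperature_preset("60C")
  wl <- seq(1420, 1460, 10)
  gen <- generate_measurement_set(preset, wl, cfg = sim_config(1e4),
                                  noise_cv = 0, seed = 92)
  meas <- gen$measurements
  cfg <- inversion_config(seed = 92L, n_photons_inversion = 1e4)
  clean <- invert_spectrum(meas, sandwich_stack(optical_properties(0.1, 10, 0.9)),
                           geom, cfg)
  bad <- meas
  bad$Rd[3] <- 0.9
  bad$Tt[3] <- 0.9
  mixed <- invert_spectrum(bad, sandwich_stack(optical_properties(0.1, 10, 0.9)),
                           geom, cfg)
  expect_equal(mixed$flag[3], "invalid_measurement")
  expect_true(is.na(mixed$mu_a_mm[3]))
  # neighbours still solve; warm-start chaining may differ marginally
  keep <- setdiff(seq_along(wl), 3)
  expect_true(all(mixed$flag[keep] == "ok"))
  expect_equal(mixed$mu_a_mm[keep], clean$mu_a_mm[keep], tolerance = 0.05)
})

test_that("a short smooth spectrum round-trips within single-point tolerances", {
  preset <- temperature_preset("60C")
  wl <- seq(1430, 1450, 5)
  gen <- generate_measurement_set(preset, wl, cfg = sim_config(2e4),
                                  noise_cv = 0, seed = 93)
  cfg <- inversion_config(seed = 93L)
  fit <- invert_spectrum(gen$measurements,
                         sandwich_stack(optical_properties(0.1, 10, 0.9)),
                         geom, cfg)
  expect_true(all(fit$flag == "ok"))
  expect_true(all(fit$converged))
  rel_a <- abs(fit$mu_a_mm - gen$truth$mu_a_mm) / gen$truth$mu_a_mm
  rel_s <- abs(fit$mu_s_mm - gen$truth$mu_s_mm) / gen$truth$mu_s_mm
  expect_lt(max(rel_a), 0.05)
  expect_lt(max(rel_s), 0.05)
  expect_lt(max(abs(fit$g - gen$truth$g)), 0.03)
  expect_equal(fit$mu_s_prime_mm, fit$mu_s_mm * (1 - fit$g))
})
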