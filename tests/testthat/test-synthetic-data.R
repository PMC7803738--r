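test_that("preset truth spectra place the absorption maxima at the printed positions", {
  # heated tissue: the 1450-band centre sits at 1441 nm
  t60 <- evaluate_truth(temperature_preset("60C"), seq(1350, 1550, 1))
  expect_lt(abs(t60$wavelength_nm[which.max(t60$mu_a_mm)] - 1441), 1)

  # room temperature: the oxyhemoglobin doublet at 545/575 nm
  t25 <- evaluate_truth(temperature_preset("25C"), seq(500, 600, 1))
  y <- t25$mu_a_mm
  ipk <- which(diff(sign(diff(y))) == -2) + 1
  expect_length(ipk, 2)
  expect_lt(abs(t25$wavelength_nm[ipk[1]] - 545), 1.5)
  expect_lt(abs(t25$wavelength_nm[ipk[2]] - 575), 1.5)

  # heated: single deoxy peak near 557 nm
  t60b <- evaluate_truth(temperature_preset("60C"), seq(500, 600, 1))
  ipk60 <- which(diff(sign(diff(t60b$mu_a_mm))) == -2) + 1
  expect_length(ipk60, 1)
  expect_lt(abs(t60b$wavelength_nm[ipk60] - 557), 1)
})

test_that("a degenerate model with no bands is a flat baseline", {
  m <- tissue_spectrum_model(baseline_mu_a = 0.01)
  tr <- evaluate_truth(m, seq(400, 1650, 50))
  expect_true(all(tr$mu_a_mm == 0.01))
  expect_true(all(tr$mu_s_mm > 0))
  expect_true(all(tr$g > 0 & tr$g < 1))
})

test_that("the wavelength grid is validated", {
  p <- temperature_preset("25C")
  expect_error(evaluate_truth(p, c(300, 500)), "380-1700")
  expect_error(evaluate_truth(p, c(500, 500)), "increasing")
  expect_error(chromophore_band(200, 10, 1), "center")
  expect_error(chromophore_band(500, -1, 1), "width")
})

test_that("the three presets keep the prescribed temperature orderings", {
  wl <- seq(400, 1650, 10)
  a25 <- evaluate_truth(temperature_preset("25C"), wl)$mu_a_mm
  a36 <- evaluate_truth(temperature_preset("36C"), wl)$mu_a_mm
  a60 <- evaluate_truth(temperature_preset("60C"), wl)$mu_a_mm
  # 25C and 36C agree within 15% everywhere
  expect_lt(max(abs(a25 - a36) / a36), 0.15)
  # heated absorption dominates over most of the grid
  expect_gt(mean(a60 > pmax(a25, a36)), 0.75)
  # steeper scattering power law and lower anisotropy when heated
  m25 <- temperature_preset("25C")$model
  m60 <- temperature_preset("60C")$model
  expect_gt(m60$scatter_b, m25$scatter_b)
  expect_lt(m60$g0, m25$g0)
})

test_that("the measurement generator is deterministic and noise-faithful", {
  p <- temperature_preset("25C")
  wl <- seq(1430, 1450, 10)
  g1 <- generate_measurement_set(p, wl, cfg = sim_config(5e3),
                                 noise_cv = 0.01, seed = 7)
  g2 <- generate_measurement_set(p, wl, cfg = sim_config(5e3),
                                 noise_cv = 0.01, seed = 7)
  expect_identical(g1, g2)

  # the noiseless path equals the raw forward tallies bit for bit
  g0 <- generate_measurement_set(p, wl, cfg = sim_config(5e3),
                                 noise_cv = 0, seed = 7)
  truth <- g0$truth
  st <- sandwich_stack(optical_properties(
    truth$mu_a_mm[2], truth$mu_s_mm[2], truth$g[2], n = truth$n[2]))
  direct <- simulate_measurements(
    st, sphere_geometry(),
    sim_config(5e3, seed = g0$measurements$seed[2]))
  expect_identical(g0$measurements$Tt[2], direct$Tt)
  expect_identical(g0$measurements$Rd[2], direct$Rd)

  # measurement table never carries truth columns
  expect_false(any(c("mu_a_mm", "mu_s_mm") %in% names(g0$measurements)))
  expect_true(all(g0$measurements$Td <= g0$measurements$Tt + 1e-12))
})

test_that("replicate spectra carry the requested coefficient of variation", {
  p <- temperature_preset("25C")
  wl <- seq(1400, 1500, 10)
  reps <- generate_replicate_spectra(p, wl, n_replicates = 40,
                                     noise_cv = 0.01, seed = 3)
  cv <- tapply(reps$mu_a_mm, reps$wavelength_nm,
               function(v) sd(v) / mean(v))
  # mean CV across wavelengths close to the nominal 1%
  expect_gt(mean(cv), 0.006)
  expect_lt(mean(cv), 0.014)
  # determinism
  reps2 <- generate_replicate_spectra(p, wl, n_replicates = 40,
                                      noise_cv = 0.01, seed = 3)
  expect_identical(reps, reps2)
})

test_that("presets survive a YAML round trip", {
  p <- temperature_preset("60C")
  f <- tempfile(fileext = ".yaml")
  write_preset_yaml(p, f)
  q <- read_preset_yaml(f)
  expect_equal(q$label, "60C")
  expect_equal(q$model$oxygen_saturation, p$model$oxygen_saturation)
  expect_equal(q$model$scatter_b, p$model$scatter_b)
  wl <- seq(1350, 1550, 25)
  expect_equal(evaluate_truth(q, wl), evaluate_truth(p, wl))
  unlink(f)
})

test_that("seed fan-out is deterministic and decorrelated", {
  s <- vapply(1:200, function(i) thermoptics:::derive_seed(42, 1, i),
              integer(1))
  expect_identical(s, vapply(1:200, function(i)
    thermoptics:::derive_seed(42, 1, i), integer(1)))
  expect_equal(length(unique(s)), 200)
  expect_true(all(s >= 1 & s < 2^31))
})
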