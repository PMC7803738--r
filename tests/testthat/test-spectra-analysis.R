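gauss_spec <- function(center, wl = seq(1350, 1550, 2), sigma = 45,
                       amp = 1, base = 0.1) {
  tibble::tibble(wavelength_nm = wl,
                 mu_a_mm = base + amp * exp(-(wl - center)^2 / (2 * sigma^2)))
}

test_that("three symmetric points interpolate to the exact vertex", {
  sp <- tibble::tibble(wavelength_nm = c(1448, 1450, 1452),
                       mu_a_mm = c(1, 2, 1))
  pk <- find_peak(sp, c(1448, 1452))
  expect_identical(pk$wavelength, 1450)
  expect_equal(pk$method, "parabolic")
})

test_that("a sampled Gaussian band is located within half a grid step", {
  sp <- gauss_spec(1441)
  expect_lt(abs(find_peak(sp, "water_1450")$wavelength - 1441), 0.5)
  expect_lt(abs(find_peak(sp, "water_1450",
                          method = "gaussian")$wavelength - 1441), 0.5)
})

test_that("boundary maxima and flat windows degrade gracefully", {
  ramp <- tibble::tibble(wavelength_nm = seq(1400, 1500, 10),
                         mu_a_mm = seq(0.1, 1.1, length.out = 11))
  pk <- find_peak(ramp, c(1400, 1500))
  expect_equal(pk$wavelength, 1500)
  expect_equal(pk$method, "discrete")

  flat <- tibble::tibble(wavelength_nm = seq(1400, 1500, 10),
                         mu_a_mm = rep(1, 11))
  pf <- find_peak(flat, c(1400, 1500))
  expect_true(pf$degenerate)
  expect_equal(pf$wavelength, 1400)  # leftmost argmax

  expect_error(find_peak(ramp, "no_such_window"), "known windows")
  expect_error(find_peak(ramp[1:2, ], c(1400, 1415)), "3 grid points")
})

test_that("peak finding is translation-equivariant and scale-invariant", {
  set.seed(99)
  for (k in 1:10) {
    centre <- runif(1, 1400, 1480)
    sp <- gauss_spec(centre)
    sp$mu_a_mm <- sp$mu_a_mm * (1 + rnorm(nrow(sp), 0, 0.02))
    base <- find_peak(sp, "water_1450")
    shift <- 30
    sp_shift <- tibble::tibble(wavelength_nm = sp$wavelength_nm + shift,
                               mu_a_mm = sp$mu_a_mm)
    moved <- find_peak(sp_shift, c(1350 + shift, 1550 + shift))
    expect_equal(moved$wavelength, base$wavelength + shift, tolerance = 1e-9)
    scaled <- sp
    scaled$mu_a_mm <- scaled$mu_a_mm * 7.3
    expect_equal(find_peak(scaled, "water_1450")$wavelength, base$wavelength,
                 tolerance = 1e-9)
  }
})

test_that("OLS gradients match the closed-form normal equations", {
  wl <- seq(400, 1500, 10)
  sp <- tibble::tibble(wavelength_nm = wl, mu_s_mm = 20 - 0.01 * (wl - 400))
  gr <- fit_gradient(sp, c(400, 1500), value = "mu_s_mm")
  expect_equal(gr$slope, -0.01, tolerance = 1e-12)
  expect_equal(gr$standard_error, 0, tolerance = 1e-10)

  # noisy line: reported SE equals the normal-equation SE to machine
  # precision, and matches OLS sampling theory across simulations
  set.seed(4)
  ses <- numeric(50); sds <- numeric(50)
  for (k in 1:50) {
    y <- 20 - 0.01 * (wl - 400) + rnorm(length(wl), 0, 0.5)
    sp$mu_s_mm <- y
    gr <- fit_gradient(sp, c(400, 1500), value = "mu_s_mm")
    X <- cbind(1, wl)
    beta <- solve(crossprod(X), crossprod(X, y))
    res <- y - X %*% beta
    s2 <- sum(res^2) / (length(wl) - 2)
    se_closed <- sqrt(s2 * solve(crossprod(X))[2, 2])
    expect_equal(gr$standard_error, se_closed, tolerance = 1e-10)
    ses[k] <- gr$standard_error
    sds[k] <- gr$slope
  }
  expect_lt(abs(sd(sds) - mean(ses)) / mean(ses), 0.3)

  expect_error(fit_gradient(sp[1, ], c(400, 410)), "3 points")
})

test_that("band shifts between replicate groups recover the injected shift", {
  wl <- seq(1350, 1550, 2)
  reps25 <- generate_replicate_spectra(temperature_preset("25C"), wl,
                                       n_replicates = 10, noise_cv = 0.01,
                                       seed = 11)
  reps60 <- generate_replicate_spectra(temperature_preset("60C"), wl,
                                       n_replicates = 10, noise_cv = 0.01,
                                       seed = 12)
  pk <- function(df) find_peak(df, "water_1450", method = "gaussian")$wavelength
  p25 <- vapply(split(reps25, reps25$replicate), pk, numeric(1))
  p60 <- vapply(split(reps60, reps60$replicate), pk, numeric(1))
  # injected centres 1454 -> 1441: a -13 nm blue shift
  sh <- estimate_shift(p60, p25, labels = c("60C", "25C"))
  expect_lt(abs(sh$estimate_difference - (-13)), 2)
  expect_lt(sh$p_value, 0.01)
  # antisymmetry of the point estimate
  rev <- estimate_shift(p25, p60, labels = c("25C", "60C"))
  expect_equal(rev$estimate_difference, -sh$estimate_difference)
})

test_that("degenerate group comparisons are flagged instead of tested", {
  one <- estimate_shift(c(1441), c(1454, 1455))
  expect_true(is.na(one$p_value))
  expect_equal(one$flag, "low_power")
  # two replicates per group, zero noise: exact shift, flagged
  z <- estimate_shift(c(1441, 1441), c(1454, 1454))
  expect_equal(z$estimate_difference, -13)
  expect_equal(z$flag, "low_power")
})

test_that("group comparison validates labels and supports permutation", {
  df <- tibble::tibble(
    temperature = rep(c("25C", "60C"), each = 6),
    replicate = rep(1:6, 2),
    value = c(rnorm(6, 1454, 1), rnorm(6, 1441, 1)))
  expect_error(compare_temperature_groups(df, c("25C", "99C")),
               "unknown temperature")
  cmp <- compare_temperature_groups(df, c("25C", "60C"), permutation = TRUE,
                                    n_permutations = 500, seed = 5)
  expect_gte(cmp$p_permutation, 0)
  expect_lte(cmp$p_permutation, 1)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$estimate_difference, 13, tolerance = 2)
  # permutation p is reproducible for a fixed seed
  cmp2 <- compare_temperature_groups(df, c("25C", "60C"), permutation = TRUE,
                                     n_permutations = 500, seed = 5)
  expect_identical(cmp$p_permutation, cmp2$p_permutation)
})

test_that("the full analysis report has one row per quantity and contrast", {
  wl <- seq(1350, 1550, 4)
  sp <- dplyr::bind_rows(lapply(c("25C", "36C", "60C"), function(lab) {
    df <- generate_replicate_spectra(temperature_preset(lab), wl,
                                     n_replicates = 3, noise_cv = 0.01,
                                     seed = match(lab, c("25C", "36C", "60C")))
    df$temperature <- lab
    df
  }))
  rep_ <- analyze_band_shifts(sp, windows = "water_1450",
                              contrasts = list(c("25C", "60C"),
                                               c("36C", "60C")),
                              gradient_window = c(1350, 1550))
  # 1 window x 2 contrasts + 2 gradient quantities x 2 contrasts
  expect_equal(nrow(rep_), 2 + 4)
  expect_setequal(unique(rep_$group_b), "60C")
})
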