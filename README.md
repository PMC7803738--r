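# thermoptics

Inverse Monte Carlo recovery of temperature-dependent tissue optical
properties from single integrating-sphere measurements.

When a thin tissue sample (here: mouse ear skin clamped between two
sapphire windows) is measured in an integrating-sphere spectrophotometer,
each wavelength yields three observables — diffuse reflectance `Rd`, total
transmittance `Tt` and diffuse transmittance `Td`, with collimated
transmittance `Tc = Tt − Td`. The tissue's absorption coefficient μa
(mm⁻¹), scattering coefficient μs (mm⁻¹) and Henyey–Greenstein anisotropy
factor g (and hence the reduced scattering coefficient μs′ = μs(1−g))
cannot be read off these signals directly: the finite beam, the 5 mm
collection port, the refractive window interfaces and light lost at the
edges of the ear all couple into them. This package is for researchers in
tissue optics who need that inversion end to end:

* a compiled Monte Carlo **forward model** of the measurement — layered
  slab, weighted photon random walk, Henyey–Greenstein scattering, Fresnel
  interfaces, edge losses, a zero-variance ballistic estimator for the
  collimated channel, and exact energy bookkeeping (all scored channels
  sum to 1 to ~1e−13);
* a **quasi-Newton inverse solver** (Broyden rank-1 Jacobian updates
  inside a dogleg trust region, common random numbers, a separable
  endgame that pins μt by inverting the deterministic collimated channel)
  recovering (μa, μs, g) per wavelength;
* a **synthetic-spectrum generator** with 25/36/60 °C mouse-ear presets:
  hemoglobin-dominated absorption in 400–950 nm, water-dominated in
  1150–1650 nm, temperature-dependent band centers (Soret 417 → 426 nm;
  oxy doublet 545/575 nm → single deoxy 557 nm; water 1192 → 1184 nm and
  1454 → 1449 → 1441 nm), power-law scattering that steepens on heating,
  and multiplicative measurement noise;
* a **spectral-analysis stage**: band-maximum localization (parabolic,
  Gaussian-fit, and a two-band fit for the oxyhemoglobin doublet),
  scattering/reduced-scattering gradients with standard errors, and
  two-stage Welch + permutation contrasts between temperature groups.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on recovered spectra.

## Worked example

Generate a noisy synthetic measurement set from the heated (60 °C)
preset over the 1450 nm water band, invert every wavelength, and locate
the recovered absorption maximum:

```r
library(thermoptics)

geom  <- sphere_geometry()                       # 1.9 mm beam, 5 mm port
stack <- sandwich_stack(optical_properties(0.1, 10, 0.9, n = 1.4))

gen <- generate_measurement_set(
  temperature_preset("60C"), seq(1350, 1550, 2),
  geom = geom, stack_template = stack,
  cfg = sim_config(n_photons = 2e4), noise_cv = 0.01, seed = 101)

fit <- invert_spectrum(gen$measurements, stack, geom,
                       inversion_config(n_photons_inversion = 2e4,
                                        seed = 202, tc_noise_floor = 0.03))
glance(fit)
#> # A tibble: 1 × 5
#>   n_wavelengths n_converged frac_converged median_residual total_forward_calls
#>           <int>       <int>          <dbl>           <dbl>               <int>
#> 1           101         101              1        0.000560                 729

find_peak(fit, "water_1450", method = "gaussian")
#> # A tibble: 1 × 6
#>   wavelength value window_lo window_hi method   degenerate
#>        <dbl> <dbl>     <dbl>     <dbl> <chr>    <lgl>
#> 1      1441.  1.40      1350      1550 gaussian FALSE
```

All 101 wavelengths converge and the recovered absorption maximum lands
at 1440.8 nm — the 1441 nm water-band position injected by the heated
preset (blue-shifted from 1454 nm at room temperature), recovered through
the full measurement-plus-inversion chain to a fraction of the 2 nm grid.
`autoplot(fit)` plots the four recovered property spectra; file-based
runs (`run_synth()`, `run_invert()`, `run_analyze()`, or the
`inst/cli/thermoptics` wrapper) write CSV results plus a seed-carrying
manifest.

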