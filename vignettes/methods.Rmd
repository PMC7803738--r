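---
title: "Recovering tissue optical properties by inverse Monte Carlo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering tissue optical properties by inverse Monte Carlo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thermoptics)
```

## The problem

Single integrating-sphere spectrophotometry of a thin tissue sample clamped
between two sapphire windows yields, at each wavelength, three observables:
diffuse reflectance $R_d$, total transmittance $T_t$ and diffuse
transmittance $T_d$, with collimated transmittance $T_c = T_t - T_d$. The
quantities of interest are the tissue's absorption coefficient $\mu_a$
(mm$^{-1}$), scattering coefficient $\mu_s$ (mm$^{-1}$) and
Henyey–Greenstein anisotropy factor $g$ (the mean cosine of the
single-scattering deflection), from which the reduced scattering
coefficient $\mu_s' = \mu_s (1-g)$ derives. No closed-form map links
$(\mu_a, \mu_s, g)$ to the sphere observables once the finite beam, finite
collection ports, refractive window interfaces and lateral losses are
taken seriously, so the package couples a Monte Carlo forward model of the
measurement to a quasi-Newton inverse solver, and exercises the chain on
synthetic mouse-ear spectra at three temperature presets (25, 36, 60 °C).

## Forward model

Photon packets are launched normally onto the stack, uniformly over a
1.9 mm beam disc, and propagated with free paths $s = -\ln \xi / \mu_t$,
$\mu_t = \mu_a + \mu_s$. Absorption decrements the packet weight by
$w\,\mu_a/\mu_t$ per collision; scattering deflects the direction by the
closed-form Henyey–Greenstein inverse CDF with a uniform azimuth; Russian
roulette (threshold $10^{-4}$, survival 0.1) terminates low weights
unbiasedly. Exits through the top face within the 5 mm sample port are
scored as $R_d$ (the order-0 specular reflection at the air/sapphire
interface is split off deterministically and scored separately, because
the instrument references reflectance to a diffuse standard); exits
through the bottom face within the port are scored as $T_t$. Packets whose
lateral excursion exceeds 6 mm — the scale of the ear beyond the port —
are terminated as edge losses.

Three design choices depart from a textbook MCML-style walk, all to make
the *inverse* problem tractable; they are unbiased estimator changes, not
model changes:

* **Deterministic ballistic cascade.** The never-scattered axial cascade
  (interface reflections plus Beer–Lambert attenuation) is evaluated
  analytically by weight splitting, once per run. Its bottom-exit weight
  *is* the collimated transmittance, so $T_c$ is a zero-variance tally and
  an exactly smooth, strictly decreasing function of $\mu_t$. The weight
  that interacts in a turbid traversal spawns a random walker at a depth
  drawn from the truncated free-path distribution. $T_d$ is reported as
  $T_t - T_c$, i.e. the scattered forward transmittance. (The 2.5°
  collimation half-angle of the open exit port remains a documented
  geometry parameter; an acceptance-cone tally of sampled exits is photon-
  count-granular precisely where the collimated signal is smallest, which
  defeats secant-based inversion.)
* **Interface splitting.** Fresnel reflection at every interface is
  handled by deterministic weight splitting — the reflected branch goes on
  a per-photon stack and is rouletted against a 0.1 weight scale — instead
  of accept/reject sampling. Under common random numbers a sampled
  reflection flip diverges an entire path; splitting shrinks the
  nonsmoothness of the forward map by roughly an order of magnitude.
* **Hierarchical RNG substreams.** Every photon, traversal and branch
  draws from its own xoshiro256++ substream keyed by a structural id. A
  divergent decision (a roulette or a branch spawn) then perturbs only its
  own subtree rather than desynchronizing the remainder of the run. Runs
  are bit-reproducible for a given seed and independent of R's RNG state.

Weight bookkeeping uses exact floating-point complements throughout, so
every run satisfies
$R_d + T_t + A + L_{\mathrm{edge}} + R_{\mathrm{spec}} + U = 1$
to about $10^{-13}$ ($A$ absorbed, $U$ unscored weight exiting outside the
collection ports).

Fixed geometry (from the modelled instrument): 1.9 mm beam, 5 mm sample
port, 25.4 mm reference-side entrance port. Model defaults chosen here:
sapphire index 1.76 (dispersion below 2% across 400–1650 nm, neglected),
window thickness 1.0 mm, tissue index 1.4, tissue thickness 0.3 mm
(mouse-ear scale), lateral extent 6 mm. Thicknesses are mandatory inputs
of `run_invert()`, never silently assumed.

## Inverse solver

Per wavelength the solver matches the simulated $(R_d, T_t, T_c)$ to the
measured triplet. Residuals: componentwise relative errors with a
$10^{-3}$ floor for $R_d$ and $T_t$, and a log-ratio
$\tfrac12 \ln(T_c^{\mathrm{sim}} / T_c^{\mathrm{meas}})$ for the
collimated channel, which through the ballistic tally is *exactly* linear
in $\mu_t$ and well scaled no matter how small $T_c$ becomes. When the
measured $T_c$ falls below `tc_noise_floor * Tt` the collimated residual
is dropped: a small $T_t - T_d$ difference is dominated by differenced
measurement noise and carries no attenuation information (set the floor to
about three times the noise CV for noisy data; the default 0 trusts exact
synthetic tallies).

The unknowns are optimized in transformed coordinates: logit of the
absorption fraction $\mu_a/\mu_t$, $\log \mu_t$, and a logit-scaled $g$.
Two properties motivate this over the obvious $(\log\mu_a, \log\mu_s)$:
bounds become unconstrained coordinates, and — decisive for Monte Carlo
objectives — at fixed $\mu_t$ the common-random-numbers trajectories are
*identical*, only the packet weights change analytically, so the weakly
identified absorption split is an exactly smooth direction of the
objective.

The algorithm is a Broyden quasi-Newton iteration inside a dogleg trust
region: the Jacobian is initialized by forward finite differences (5%
relative step), maintained by rank-1 secant updates, refreshed by finite
differences after two consecutive negative reduction ratios, every ten
iterations (secant updates slowly corrupt the small absorption-split
column), and when the trust radius collapses. Steps are accepted on the
usual actual-versus-predicted reduction ratio; the radius shrinks by 4 on
poor steps and doubles on full successful ones. Common random numbers
(`seed_policy = "fixed-per-inversion"`) make the whole fit deterministic
and bit-reproducible.

A structured endgame then exploits the model's separability: $\mu_t$ is
pinned by inverting the deterministic ballistic chain for the measured
$T_c$ (no forward calls), and the remaining $2\times2$ system in
(absorption split, $g$) is polished by damped Newton steps with fresh
finite-difference Jacobians. Spectrum inversion proceeds wavelength by
wavelength with warm starts from the previous solution (falling back to
the coarse initial guess when the previous residual exceeded
`warm_start_max_residual`), and reuses one seed across wavelengths so that
residual Monte Carlo bias varies smoothly with wavelength instead of
adding independent per-wavelength noise — which matters when band maxima
are located on the recovered spectrum.

The initial guess inverts $T_c$ through a Fresnel-corrected single-pass
Beer–Lambert relation for $\mu_t$, then grid-searches 25 log-spaced
(absorption fraction × scale) candidates at $g = 0.9$ against $(R_d,T_t)$,
breaking ties toward the smallest $\mu_a$; with no collimated signal it
falls back to a log-spaced grid over all three parameters.

### What the solver can and cannot identify

$T_c$ pins $\mu_t$ sharply ($\delta\mu_t\,d = \delta \ln T_c$), so
$\mu_s$ and, through $R_d/T_t$, $g$ are recovered to about 1% and 0.003
under 1% measurement noise. $\mu_a$ rides on the absorbed fraction
$\approx \mu_a \bar L$ (path length $\bar L \sim 0.4$–1 mm here): when
$\mu_a \bar{L}$ is of the order of the measurement noise, no algorithm can
do better than a noise-equivalent error of roughly
$\mathrm{noise}/(\mu_a \bar L)$ relative. At $\mu_a = 0.03$ mm$^{-1}$ and
1% noise this is a ~40% error; at $\mu_a \gtrsim 0.3$ mm$^{-1}$ (the
hemoglobin and water bands that the temperature analysis tracks) it is a
few percent. The same limit, with the residual nonsmoothness floor of the
common-random-numbers map taking the role of the noise, governs the
noise-free round-trip grid: cells at $\mu_a = 0.01$ mm$^{-1}$ recover
$\mu_a$ only to 5–35% even though $\mu_s$ and $g$ are essentially exact.

## Synthetic spectra

`temperature_preset()` ships three ground-truth models. Absorption is a
flat baseline plus Gaussian bands: oxy- and deoxyhemoglobin mixed by an
oxygen saturation, plus two water bands; scattering follows a power law
$\mu_s = a (\lambda/500\,\mathrm{nm})^{-b}$; $g$ has a small linear trend.
Band centers sit at the reported peak positions for each condition —
Soret 417 nm (oxygenated) vs 426 nm (deoxygenated); the 545/575 nm
oxyhemoglobin doublet vs a single 557 nm deoxy band plus a 905 nm deoxy
band; water bands at 1192/1454 nm (25 °C), 1192/1449 nm (36 °C) and
1184/1441 nm (60 °C). Band widths (Soret $\sigma$ 15 nm, visible bands
10 nm, water bands 35 and 45 nm) keep adjacent reported maxima resolvable
on a 1 nm grid; amplitudes were chosen once so that $\mu_a$ spans
~0.09–5 mm$^{-1}$ and $\mu_s$ ~4–37 mm$^{-1}$, typical of skin — they are
model configuration, not literature claims. The heated preset has near-
zero saturation, 1.5×/1.3× blood/water amplitude scales (shrinkage
concentrates chromophores), a steeper scattering exponent (1.55 vs 1.20)
and a lower baseline anisotropy (0.885 vs 0.920). The 36 °C saturation
(0.90 vs 0.93) and the 0.09 mm$^{-1}$ baseline were set from an analytic
check that the 25 °C and 36 °C spectra stay within 15% of each other
everywhere while the heated spectrum exceeds both over most of the grid.

`generate_measurement_set()` forward-simulates the truth per wavelength
(independent per-wavelength substreams fanned out from one master seed)
and applies independent multiplicative Gaussian noise $(1+\epsilon)$,
$\epsilon \sim N(0, \mathrm{cv}^2)$, to $R_d$, $T_t$, $T_d$, re-clipping
to $[0,1]$ and to $T_d \le T_t$; truth and measurements are kept in
separate tables so recovery scoring can never touch the truth by
accident. `generate_replicate_spectra()` emulates across-animal
variability of *recovered* spectra directly (multiplicative noise on the
property curves) for the statistical stage, at a tiny fraction of the
cost of a full per-replicate inversion. What the generator does **not**
emulate: literature extinction spectra (band shapes are idealized
Gaussians), melanin (albino animals), chromophore coupling, instrument
stray light and sphere-wall corrections, or wavelength-dependent window
dispersion. Passing the pipeline on these spectra therefore demonstrates
the correctness and statistical calibration of the chain, not the
field accuracy of any particular optical-property value.

## Band shifts and gradients

`find_peak()` locates an absorption maximum in a named window (defaults:
soret 400–470, oxy doublet 520–600, deoxy NIR 860–950, water 1120–1260
and 1350–1550 nm). `method = "parabolic"` refines the discrete argmax by
three-point parabolic interpolation when the stencil is concave (ties
interpolate to the midpoint; boundary maxima and flat windows are
returned unrefined, the latter flagged degenerate). `method = "gaussian"`
fits a Gaussian band on a linear background by Levenberg–Marquardt, with
the width and centre constrained to the window so that a noisy spectrum
cannot trade the band against the background; `find_doublet()` fits two
Gaussians on a linear background for overlapping bands (the oxyhemoglobin
alpha/beta doublet), where single-band fits in sub-windows are biased
outward by the neighbouring band's tail. The
choice matters for noisy single spectra: on a $\sigma = 45$ nm band with
~2% per-wavelength noise the discrete argmax wanders by about
$\sigma\sqrt{5\,\epsilon} \approx \pm 10$ nm, while the Gaussian fit
averages the whole window and localizes the center to a fraction of a
nanometre. The original measurements underlying the study conditions were
averaged over 10–12 animals before peaks were read off; a single
synthetic spectrum needs the regression estimator instead, so the
pipeline and the acceptance analysis use `"gaussian"`.

Scattering and reduced-scattering gradients are ordinary least-squares
slopes versus wavelength (`fit_gradient()`, via `lm()`), with their
standard errors. Group contrasts use a two-stage summary analysis: each
replicate is reduced to one number (a peak wavelength or a gradient), and
groups are compared by a Welch test on the summaries — for balanced
summaries this is equivalent to a random-intercept mixed model, which it
replaces deliberately — with an optional seeded permutation test
($\ge 10^4$ label permutations) as a distribution-free check. Groups with
fewer than two replicates, or two degenerate ones, are flagged
`low_power` instead of tested.

## Problem sizes and numerical choices

Defaults used by the shipped analyses, chosen as a deliberate accuracy/
cost point on one CPU: $2\times10^4$ photons per forward call for both
measurement generation and inversion (the water and Soret windows), and
$5\times10^4$ for the weak visible/NIR hemoglobin bands, whose
0.3 mm$^{-1}$ amplitude on a ~0.4 mm$^{-1}$ background needs roughly
twice lower Monte Carlo noise; residual tolerance $10^{-3}$ for noise-free work and 0.025 (the 1%-noise
residual floor: polishing a noisy spectrum below its noise changes nothing)
for the shipped noisy-pipeline analyses; 2 nm analysis grids for the
acceptance runs and 4–6 nm grids in the test suite. Degenerate inputs are handled explicitly: matched-index interfaces
short-circuit to zero reflectance; total internal reflection returns
reflectance exactly 1; $\mu_s = 0$ reduces collimated transmission to
Beer–Lambert exactly (the ballistic cascade); zero-measurement windows
(measured $T_c$ under the configured noise floor) drop the collimated
residual rather than fit noise; physically impossible rows
($R_d + T_t > 1$) are flagged per wavelength and skipped without
aborting a spectrum.

## Known limitations

* $\mu_a$ below ~0.05 mm$^{-1}$ in a 0.3 mm sample is identified only to
  tens of percent at these photon budgets (see above); the temperature
  analysis is unaffected because its bands are 3–60× stronger.
* The collimated channel is defined as *unscattered* transmittance; an
  instrument's open-port realization also passes a small near-forward
  scattered component, which here ends up in $T_d$.
* One homogeneous tissue layer (as in the modelled experiment); no
  polarization; no phase functions beyond Henyey–Greenstein; no
  sphere-wall radiometry corrections.
* The permutation test resamples labels, not spectra: it inherits the
  two-stage reduction's assumption that one summary per replicate is
  exchangeable under the null.
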