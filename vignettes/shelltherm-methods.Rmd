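---
title: "Methods: solar-weighted shell reflectivity and phylogenetic thermal ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solar-weighted shell reflectivity and phylogenetic thermal ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

shelltherm implements the analysis chain behind a comparative study of
intertidal gastropod shells: how much incident solar energy a shell
reflects, whether that reflectivity tracks the species' microhabitat
(sun-exposed rock tops versus crevices and overhangs) and the shell's
state (wet just after emersion versus dry), and whether reflectivity
measurably slows heating in the field. This vignette explains the models
and the numerical choices, states the package's defaults and why they
were chosen, and describes what the synthetic-data generators do and do
not emulate.

## Solar-weighted reflectivity

A reflectance spectrum $S(\lambda)$ (fraction of light reflected
relative to a 99% white standard) is summarised as *reflectivity*: the
mean reflectance weighted by the solar spectral irradiance
$I(\lambda)$,

$$R = \frac{\int_i^n S(\lambda)\, I(\lambda)\, d\lambda}
           {\int_i^n I(\lambda)\, d\lambda} \times 100\,.$$

$R$ is computed in three bands: total (300–1700 nm), UV-visible
(300–700 nm) and near-infrared (NIR, 700–1700 nm). The NIR band matters
because roughly half of incident solar energy arrives there, invisible
to most animal visual systems, so NIR reflectance is expected to evolve
under thermoregulatory selection rather than visual selection.

Numerics: both curves are linearly interpolated onto a common 1 nm grid
and integrated with the trapezoid rule; a dense-grid (0.1 nm Riemann
sum) oracle in the test suite bounds the integration error below 0.05
percentage points. Because adjacent trapezoid integrals add exactly, the
three bands satisfy the mixture identity
$R_{tot} = (E_{uv} R_{uv} + E_{nir} R_{nir}) / (E_{uv} + E_{nir})$
to machine precision, where $E_b$ is the band irradiance integral. With
the bundled irradiance table the two energy weights are nearly equal
(50.3% / 49.7%), so total reflectivity is approximately the plain
average of the band values.

### The bundled solar spectrum

`load_solar()` reads a packaged reference irradiance table laid out like
the standard reference solar spectrum (wavelength, extraterrestrial,
global tilt, direct + circumsolar). The file is *synthetic*: it is
generated by `solar_reference_model()` from a Planck extraterrestrial
curve attenuated at air mass 1.5 by parametric Rayleigh, aerosol, ozone,
oxygen, carbon dioxide and water-vapour transmittance terms, with two
scale factors calibrated so the global-tilt band energy fractions
reproduce the standard's published values: the UV-visible share of
300–1700 nm is 50.3%, and 300–1700 nm carries 98.9% of the 300–2600 nm
solar range. Those two fractions are the only properties of the
reference table the analysis depends on (they set the band weights in
the mixture identity and the energy-fraction constants); fine spectral
structure such as the exact depths of individual water-vapour bands is
not reproduced, and absolute irradiance levels are irrelevant because
reflectivity is invariant to rescaling the irradiance curve (a property
the tests assert). The 98.9% fraction is computed against the 300–2600
nm solar range; `band_solar()` exposes that reference band and
alternatives can be computed directly with `band_energy_fraction()`.

## Spectral processing

Shell reflectance is acquired on two instruments (roughly 300–1000 nm
and 1000–1700 nm). `splice()` joins them at 1000 nm, rescaling the NIR
segment multiplicatively so the mean reflectance over the common
±10 nm window matches the UV-visible instrument; the window is
restricted to the overlap of the two measured ranges and both curves are
interpolated onto the same grid there, so a continuous underlying curve
is recovered exactly. A multiplicative (not additive) correction was
chosen because instrument steps in standard-relative reflectance are
gain-like; continuity is required for the reflectivity integral.

`smooth_spectrum()` applies one pass of a local-linear smoother with
tricube weights (`stats::loess`, degree 1) with the span given as the
fraction of points in each window, default 0.10. Local-linear smoothing
reproduces constants and straight lines exactly, which the tests use as
oracles. Negative smoothed values are clamped to zero (a physical
floor); values above 1 are kept, since reflectance relative to a white
standard can legitimately exceed it. Smoothing is applied after
splicing by default — the joined curve is smoothed once on its common
grid — with `smooth_first = TRUE` available to smooth each instrument
range first; for smooth shell spectra the two orders agree closely
(tested to 1e-3).

## The phylogenetic mixed model

Reflectivity (or residual heating rate) is modelled as

$$y = X\beta + Z_s u + Z_i v + \varepsilon, \qquad
  u \sim \mathcal N(0, \sigma_s^2 A), \quad
  v \sim \mathcal N(0, \sigma_i^2 I), \quad
  \varepsilon \sim \mathcal N(0, \sigma^2 I),$$

where $A$ is the Brownian-motion correlation matrix of the species
tree: the shared root-to-tip path length of each species pair divided by
tree depth. The tree is validated as ultrametric (relative tolerance
1e-3 of depth) and scaled to depth 1 before building $A$, so variance
components are comparable across trees with arbitrary time units. The
species effect carries the full phylogenetic covariance; no additional
independent species term is added (the standard phylogenetic-regression
construction — an independent term can be emulated by passing
`tree = NULL`).

Fixed effects use treatment coding. For the reflectivity models the
reference levels are *sheltered* and *wet*, so the intercept is the
expected reflectivity of a wet-shelled gastropod from a sheltered
microhabitat and the other coefficients are differences from it; the
NIR model adds UV-visible reflectivity as a covariate on its raw
percent scale (primary variant) or models the residuals of NIR on
UV-visible (sensitivity variant, `nir_variant = "residual"`). The
heating model uses reference *dry* with total reflectivity (percent)
and shell length (mm) entered uncentred, matching the printed-table
interpretation of its intercept.

Priors are weakly informative: Normal(0, 10) on the intercept,
Normal(0, 50) on slopes, and half-Student-t(3, 0, 20) on the three
standard deviations. On the percent reflectivity scale these are broad
relative to plausible effects (reflectivities live in 0–100).

### Sampler

`fit_pgmm()` is a Metropolis-within-Gibbs sampler written for this
model family:

* all location parameters $(\beta, u, v)$ are drawn **jointly** from
  their exact multivariate-normal full conditional, via the Cholesky
  factor of the combined precision matrix. Drawing the blocks jointly
  rather than sequentially removes the strong intercept/random-effect
  posterior correlations and brings the fixed-effect effective sample
  sizes close to the number of kept draws;
* each standard deviation is updated by univariate slice sampling
  (stepping-out with shrinkage) on the log scale, with the half-t prior
  and the log-scale Jacobian in the target. Slice sampling needs no
  tuning and is rejection-free, which keeps runs deterministic under a
  fixed seed.

Defaults are two chains of 6000 iterations with the first 2000
discarded; chain $c$ is seeded `seed + c - 1`, so results are exactly
reproducible. Between-individual and residual standard deviations mix
more slowly than the location parameters (each individual contributes
only a wet and a dry measurement, so $\sigma_i$ and $\sigma$ trade
off); their effective sample sizes are reported and a message is issued
below 2000, but the fixed-effect inferences the analysis reports are
insensitive to this.

Correctness is established two ways in the test suite: with variance
components held fixed, posterior means of $\beta$ must match the
closed-form generalized-least-squares solution
$(X' V^{-1} X)^{-1} X' V^{-1} y$ computed by independent dense linear
algebra (`gls_oracle()`); and with no data the sampler must reproduce
its priors (quantile checks on the Normal and half-t marginals).

### Diagnostics

`ess()` implements $n / (1 + 2\sum_k \rho_k)$ with Geyer's initial
positive sequence truncation (consecutive autocorrelation pairs are
summed while positive); a zero-variance chain returns 1 with a warning.
The AR(1) closed form $n(1-\rho)/(1+\rho)$ is the test oracle.
`split_rhat()` halves each chain and compares between- to within-half
variance; fits warn when any value exceeds 1.1. Summaries report the
posterior mean, empirical 2.5% and 97.5% quantiles, pooled-chain ESS
and split R-hat per parameter.

## The heating-rate analysis

Field heating rate is the change in mean shell surface temperature over
the sun-exposure interval, in °C min⁻¹. Conductive heat gain from the
rock is removed in a first stage by regressing heating rate on nearby
rock temperature (OLS, pooled across shell states by default;
`per_state = TRUE` fits within state) and passing the residuals to the
mixed model. The two-stage procedure is retained deliberately — it is
the analysis the study describes — rather than absorbing rock
temperature as a covariate of the mixed model; because rock temperature
is independent of the covariates, the second-stage coefficients are
unbiased, and the tests verify the noiseless limit against a joint OLS
including the rock term. `predicted_difference()` converts the
reflectivity slope into an accumulated temperature gap:
with the reference slope of −0.02 °C min⁻¹ per percent, a 40-point
reflectivity difference over 2 minutes yields 1.6 °C.

## Synthetic data: what it emulates

The generators define the study conditions used by the recovery tests;
their defaults are fixed and are not tuning knobs.

`gen_reflectivity_study()`: 19 species on a simulated pure-birth (Yule)
tree, 3 individuals per species, each measured wet and dry (114
records); 10 of 19 species exposed. Fixed effects default to the
published posterior means of the total-reflectivity model (13.11, 9.04,
3.71, 7.44) and the UV-visible model (9.56, 5.26, 2.71, 5.42). Variance
components default to 5 (species), 2 (individual) and 2 (residual)
percentage points: the study reports intraspecific variation
"substantially smaller" than interspecific variation without printing
values, and this ordering encodes that while keeping posterior
uncertainties comparable to the printed credible intervals. NIR is
derived from the band mixture identity, so every generated record obeys
it exactly; the cross-band correlation of the random components is
0.76, calibrated once so the squared UV-visible/NIR correlation
averages ≈ 0.52 across replicates, the value the study reports.

`gen_heating_study()`: 11 species with per-species counts
(2, 5, 9, 9, 10, 10, 10, 10, 10, 10, 10) — 95 individuals measured wet
and dry (190 records); exposure times uniform on 135–195 s; rock
temperature Normal(30, 1.2) °C; species reflectivities spread over
10–50%. Heating rates are built from a baseline of 2.5 °C min⁻¹, a
rock-conduction slope of 0.15 °C min⁻¹ per °C (a package choice — the
study does not print one — sized so conduction explains a comparable
share of variance to the covariates), the published effect sizes
(−0.02 per percent reflectivity, −0.46 wet, −0.02 per mm, zero
interaction), and variance components 0.15 / 0.10 / 0.20 °C min⁻¹
chosen so the synthetic posterior uncertainties match the printed
credible-interval widths. End temperatures are back-computed from the
rate, so reading records through `heating_rate()` is exact.

What the generators do **not** emulate: measurement error in the
spectra themselves (reflectivities are drawn directly from the mixed
model), phylogenetic signal in habitat assignment (habitat is assigned
at species level uniformly at random), behavioural or evaporative
components of field heat exchange, and intraspecific reflectivity
variation in the heating study (reflectivity is a species-level value
there, as in the published analysis). Passing recovery tests therefore
demonstrates that the estimation chain is unbiased and calibrated under
the model's own assumptions, not that the model is correct for real
shells.

## Problem sizes and seeds

The recovery experiments average posterior means over 10 seeded
replicates at the full study sizes (114 and 190 records) with the
default chain settings; the credible-interval calibration check uses 50
replicates at a reduced size (8 species × 2 individuals × 2 states,
chains of 1500) — sizes chosen to give stable Monte-Carlo summaries
while keeping the default test run short. All randomness flows from
explicit integer seeds; generators and sampler are bit-reproducible
given (config, seed).

## Known limitations

* The bundled solar table is a calibrated synthetic stand-in, adequate
  for band-energy weighting but not for line-resolved radiometry.
* The sampler targets this model family only (Gaussian response, two
  random effects); there is no non-Gaussian support and no
  Hamiltonian/NUTS fallback for stiffer posteriors.
* $\sigma_i$/$\sigma$ mix slowly when individuals contribute two
  measurements; fixed-effect inference is unaffected, but variance
  component intervals at the default chain length are conservative.
* Ultrametricity is required; non-clock trees are rejected rather than
  transformed (no Pagel's λ or OU rescaling).
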