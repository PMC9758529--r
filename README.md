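# shelltherm

Intertidal gastropods can overheat during summer low tides. A shell that
reflects more of the incident solar spectrum — including the
near-infrared (NIR, 700–1700 nm) half of solar energy that no predator
can see — absorbs less energy and heats more slowly. `shelltherm` is an
R package for the complete analysis chain behind that question:

* **Spectral processing** — read two-instrument reflectance spectra
  (UV-visible 300–1000 nm, NIR 1000–1700 nm), splice them with a
  continuity correction, resample and smooth (loess, span 0.10).
* **Solar-weighted reflectivity** — summarise each spectrum as
  $R = \int S(\lambda) I(\lambda) d\lambda \,/\, \int I(\lambda)
  d\lambda$ over the total (300–1700 nm), UV-visible (300–700 nm) and
  NIR (700–1700 nm) bands, against a bundled reference solar irradiance
  table (a calibrated synthetic stand-in for the standard global-tilt
  spectrum; see the methods vignette).
* **Phylogenetic mixed models** — Bayesian Gaussian mixed models
  $y = X\beta + Z_s u + Z_i v + \varepsilon$ with a species effect
  structured by the Brownian correlation matrix of an ultrametric tree
  ($u \sim \mathcal N(0, \sigma_s^2 A)$), an individual effect, weak
  Normal/half-Student-t priors, fitted by a Gibbs + slice MCMC sampler
  (2 chains × 6000 iterations, burn-in 2000), with ESS and split R-hat
  diagnostics.
* **Field heating analysis** — heating rates from paired thermal-image
  temperatures, rock-temperature residualization for conductive heat
  gain, and the heating mixed model (reflectivity, shell state, shell
  length, reflectivity × state).
* **Synthetic data** — Yule tree simulation and calibrated generators
  for reflectivity and heating studies that carry their generating
  truth, so every stage is testable without the original raw data.

## Worked example

Simulate a reflectivity study at the calibrated defaults (19 species on
a Yule tree, 3 individuals each, wet and dry) and fit the
total-reflectivity model:

```r
library(shelltherm)

sol <- load_solar()
round(100 * band_energy_fraction(sol, band_uv(), band_total()), 1)
#> [1] 50.3

g   <- gen_reflectivity_study(seed = 1)
fit <- fit_reflectivity_model(g$records, g$tree, band = "total", seed = 1)
fit$summary
#>                      parameter estimate ci_low ci_high  ess  rhat
#>                      Intercept    13.19   7.51   18.52 7556 1.000
#>              Habitat (Exposed)     8.71   6.02   11.33 8000 1.000
#>                    State (Dry)     3.11   2.02    4.19 8000 1.000
#>  Habitat (Exposed):State (Dry)     8.10   6.62    9.57 8000 1.000
#>                   SD (Species)     5.82   3.75    9.06 3346 1.001
#>                SD (Individual)     2.01   1.01    2.81  290 1.009
#>               Sigma (Residual)     2.04   1.68    2.55  492 1.006
```

The estimates are posterior means with 95% credible intervals. The
intercept is the expected total reflectivity (percent) of a wet-shelled
gastropod from a sheltered microhabitat; the remaining fixed effects are
differences from it, so this run recovers the generating values
(13.11, 9.04, 3.71, 7.44) within posterior uncertainty: dry shells of
exposed species come out `13.19 + 8.71 + 3.11 + 8.10 = 33.1%` versus
`13.19 + 3.11 = 16.3%` for sheltered ones.

Spectra whose band reflectivities hit prescribed targets can be
generated and verified through the same integral:

```r
s <- gen_spectrum(20, 45, sol, seed = 1)
solar_reflectivity(s, sol, band_uv())   # 20.01
solar_reflectivity(s, sol, band_nir())  # 44.99
solar_reflectivity(s, sol, band_total())# 32.42  (energy-weighted mix)
```

A heating experiment works the same way: `gen_heating_study(seed = 1)`
simulates 95 individuals from 11 species measured wet and dry, and
`fit_heating_model()` residualizes heating rate on rock temperature and
fits the mixed model.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/shelltherm.R simulate heating --seed 5 --out runs/sim
Rscript inst/cli/shelltherm.R fit total --config cfg.yaml
Rscript inst/cli/shelltherm.R report --out runs/sim
```

Configuration is a flat YAML file (paths, band edges, smoothing span,
solar variant, chain settings, seeds); CLI flags override file values.

## Package layout

```
R/                 spectra, solar, reflectivity, phylo, pgmm,
                   diagnostics, heating, synthetic, models, pipeline
inst/extdata/      solar_reference_synthetic.csv (bundled irradiance)
inst/cli/          command-line wrapper
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (models, defaults, limitations)
scripts/           acceptance script, solar-table regeneration
```
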