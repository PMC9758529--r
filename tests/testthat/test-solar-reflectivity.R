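test_that("bundled solar table covers the reference range and validates", {
  sol <- solar_fixture()
  expect_s3_class(sol, "solar_spectrum")
  expect_lte(min(sol$wavelength_nm), 300)
  expect_gte(max(sol$wavelength_nm), 2600)
  expect_true(all(sol$irradiance >= 0))
  expect_identical(sol$variant, "global-tilt")
})

test_that("extraterrestrial variant integrates above global tilt", {
  et <- load_solar(variant = "extraterrestrial")
  gt <- solar_fixture()
  int <- function(s) {
    wl <- s$wavelength_nm; keep <- wl >= 300 & wl <= 2600
    x <- wl[keep]; y <- s$irradiance[keep]
    sum((y[-1] + y[-length(y)]) * diff(x)) / 2
  }
  expect_gt(int(et), int(gt))
})

test_that("custom two-column solar files are accepted as variant custom", {
  path <- tempfile(fileext = ".csv")
  wl <- seq(280, 2620, by = 4)
  write.csv(data.frame(wavelength_nm = wl, irradiance = rep(1, length(wl))),
            path, row.names = FALSE)
  sol <- load_solar(path)
  expect_identical(sol$variant, "custom")
  expect_error(load_solar(variant = "nope"))
})

test_that("solar validation rejects gaps and missing coverage", {
  wl <- c(seq(280, 1000, 4), seq(1020, 2620, 4))  # 20 nm gap
  expect_error(solar_spectrum(wl, rep(1, length(wl))),
               class = "solar_coverage")
  expect_error(solar_spectrum(seq(400, 2600, 2), rep(1, 1101)),
               class = "solar_coverage")
})

test_that("band energy fractions behave and match the calibrated constants", {
  sol <- solar_fixture()
  expect_equal(band_energy_fraction(sol, band_total(), band_total()), 1.0)
  f_uv <- band_energy_fraction(sol, band_uv(), band_total())
  expect_equal(f_uv, 0.503, tolerance = 0.003 / 0.503)
  f_cov <- band_energy_fraction(sol, band_total(), band_solar())
  expect_equal(f_cov, 0.989, tolerance = 0.01 / 0.989)
  expect_error(band_energy_fraction(sol, band_total(), band_uv()),
               class = "band_nesting")
})

test_that("solar-weighted reflectivity of a constant is that constant", {
  sol <- solar_fixture()
  s <- constant_spectrum(0.30)
  for (b in list(band_total(), band_uv(), band_nir()))
    expect_equal(solar_reflectivity(s, sol, b), 30.0, tolerance = 1e-9)
})

test_that("a UV-only reflector weighted over the total band gives the UV energy share", {
  sol <- solar_fixture()
  wl <- seq(300, 1700, by = 0.5)
  s <- spectrum(wl, as.numeric(wl < 700))
  r <- solar_reflectivity(s, sol, band_total())
  f_uv <- 100 * band_energy_fraction(sol, band_uv(), band_total())
  expect_equal(r, f_uv, tolerance = 0.01)
  expect_equal(r, 50.3, tolerance = 0.5 / 50.3)
})

test_that("trapezoid integration at 1 nm agrees with a dense Riemann sum", {
  sol <- solar_fixture()
  set.seed(21)
  wl <- seq(300, 1700, by = 2)
  vals <- 0.3 + 0.2 * sin(wl / 150) + 0.05 * sin(wl / 37)
  s <- spectrum(wl, vals)
  r1 <- solar_reflectivity(s, sol, band_total())
  grid <- seq(300, 1700, by = 0.1)
  sr <- approx(wl, vals, grid)$y
  ir <- approx(sol$wavelength_nm, sol$irradiance, grid)$y
  r_dense <- 100 * sum(sr * ir) / sum(ir)
  expect_lt(abs(r1 - r_dense), 0.05)
})

test_that("reflectivity respects spectrum bounds, monotonicity and irradiance rescaling", {
  sol <- solar_fixture()
  set.seed(8)
  for (rep in 1:10) {
    wl <- seq(300, 1700, by = 5)
    vals <- runif(length(wl), 0, 1)
    s <- spectrum(wl, vals)
    r <- solar_reflectivity(s, sol, band_total())
    expect_gte(r, 100 * min(vals) - 1e-9)
    expect_lte(r, 100 * max(vals) + 1e-9)

    # pointwise increase never decreases R
    bump <- runif(length(wl), 0, 0.2)
    r_up <- solar_reflectivity(spectrum(wl, vals + bump), sol, band_total())
    expect_gte(r_up, r - 1e-9)

    # invariance to uniform irradiance rescaling
    sol2 <- solar_spectrum(sol$wavelength_nm, 3.7 * sol$irradiance, "scaled")
    expect_equal(solar_reflectivity(s, sol2, band_total()), r,
                 tolerance = 1e-12)
  }
  expect_error(solar_reflectivity(spectrum(400:800, runif(401)), sol,
                                  band_total()),
               class = "band_coverage")
})

test_that("patch averaging is the unweighted mean", {
  expect_equal(patch_average(20), 20)
  expect_equal(patch_average(c(10, 30)), 20)
  expect_equal(patch_average(c(5, 10, 30)), 15)
  expect_error(patch_average(numeric(0)), class = "patch_empty")
})

test_that("reflectivity table averages patches and joins metadata", {
  sol <- solar_fixture()
  meta <- data.frame(specimen = "s1", species = "species_01",
                     habitat = "exposed")
  specs <- list(
    constant_spectrum(0.2, meta = list(specimen = "s1", patch = "a",
                                       state = "wet")),
    constant_spectrum(0.4, meta = list(specimen = "s1", patch = "b",
                                       state = "wet")),
    constant_spectrum(0.5, meta = list(specimen = "s1", patch = "a",
                                       state = "dry")),
    constant_spectrum(0.5, meta = list(specimen = "s1", patch = "b",
                                       state = "dry")))
  tab <- build_reflectivity_table(specs, sol, meta)
  expect_equal(nrow(tab), 2)
  wet <- tab[tab$state == "wet", ]
  expect_equal(wet$R_total, 30, tolerance = 1e-9)
  expect_equal(wet$R_uv, 30, tolerance = 1e-9)
  dry <- tab[tab$state == "dry", ]
  expect_equal(dry$R_nir, 50, tolerance = 1e-9)

  expect_error(build_reflectivity_table(specs, sol,
    data.frame(specimen = "s1", species = "x", habitat = "reef")),
    class = "habitat_unknown")

  # missing state warns but still emits the present record
  expect_warning(
    tab1 <- build_reflectivity_table(specs[1:2], sol, meta),
    class = "missing_state")
  expect_equal(nrow(tab1), 1)
})

test_that("band mixture identity holds exactly on computed records", {
  sol <- solar_fixture()
  e_uv <- band_energy_fraction(sol, band_uv(), band_total())
  set.seed(31)
  for (rep in 1:8) {
    wl <- seq(300, 1700, by = 2)
    s <- spectrum(wl, runif(length(wl), 0, 1))
    r_tot <- solar_reflectivity(s, sol, band_total())
    r_uv <- solar_reflectivity(s, sol, band_uv())
    r_nir <- solar_reflectivity(s, sol, band_nir())
    expect_equal(r_tot, e_uv * r_uv + (1 - e_uv) * r_nir, tolerance = 1e-6)
    # with the calibrated energy split this is close to the plain average
    expect_equal(r_tot, (r_uv + r_nir) / 2, tolerance = 0.02 * max(r_tot, 1))
  }
})

test_that("NIR-on-UV residualization matches the normal-equations oracle", {
  rec <- data.frame(R_uv = c(4, 9, 14, 18, 25, 30),
                    R_nir = c(6, 15, 20, 31, 42, 50))
  out <- uv_nir_residuals(rec)
  oracle <- ols_oracle(rec$R_uv, rec$R_nir)
  expect_equal(out$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(out$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(out$residuals, oracle$residuals, tolerance = 1e-12)
  expect_lt(abs(sum(out$residuals)), 1e-9)

  # exact linear relation: zero residuals, r^2 = 1
  rec2 <- data.frame(R_uv = 1:6, R_nir = 2 * (1:6))
  out2 <- suppressWarnings(uv_nir_residuals(rec2))  # perfect-fit lm note
  expect_lt(max(abs(out2$residuals)), 1e-12)
  expect_equal(out2$r_squared, 1)

  expect_error(uv_nir_residuals(data.frame(R_uv = rep(3, 5),
                                           R_nir = rnorm(5))),
               class = "residual_degenerate")
})
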