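#' Wavelength bands
#'
#' A `band` is a pair of integration limits in nm used both for the
#' solar-weighted reflectivity integral and for band energy fractions.
#' The conventional analysis bands are total (300--1700 nm), UV-visible
#' (300--700 nm) and near-infrared (700--1700 nm); the reference solar
#' range is 300--2600 nm.
#'
#' @param lo_nm,hi_nm integration limits in nm, `lo_nm < hi_nm`, both
#'   within 300--2600.
#' @return An object of class `band`.
#' @export
#' @examples
#' band(300, 700)
band <- function(lo_nm, hi_nm) {
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || lo_nm >= hi_nm)
    st_stop("band_invalid", "band limits must satisfy lo < hi")
  if (lo_nm < 300 || hi_nm > 2600)
    st_stop("band_invalid", "band limits must lie within [300, 2600] nm")
  structure(list(lo_nm = lo_nm, hi_nm = hi_nm), class = "band")
}

#' @rdname band
#' @export
band_total <- function() band(300, 1700)
#' @rdname band
#' @export
band_uv <- function() band(300, 700)
#' @rdname band
#' @export
band_nir <- function() band(700, 1700)
#' @rdname band
#' @export
band_solar <- function() band(300, 2600)

#' Synthetic reference solar irradiance spectrum
#'
#' Generates the bundled reference solar spectrum from a simple physical
#' model: a Planck extraterrestrial curve at the solar effective
#' temperature, attenuated at air mass 1.5 by parametric Rayleigh,
#' aerosol, ozone, oxygen, carbon dioxide and water-vapour transmittance
#' terms, split into direct and diffuse components. This is a synthetic
#' stand-in laid out like the standard reference table (wavelength,
#' extraterrestrial, global tilt, direct + circumsolar); its water-vapour
#' band depths are calibrated so the global-tilt band energy fractions
#' reproduce the standard's published values (UV-visible share of
#' 300--1700 nm = 50.3%; share of 300--2600 nm covered by 300--1700 nm =
#' 98.9%). It is not the measured standard table.
#'
#' @param wavelength_nm wavelength grid in nm; default 280--1702 nm in
#'   2 nm steps then 1705--2600 nm in 5 nm steps.
#' @param water_scale multiplier on water-vapour band depths below
#'   1700 nm (calibrated default).
#' @param tail_scale multiplier on absorption beyond 1700 nm
#'   (calibrated default).
#' @return A data.frame with columns `wavelength_nm`, `extraterrestrial`,
#'   `global_tilt`, `direct_circumsolar` (W m-2 nm-1).
#' @export
solar_reference_model <- function(wavelength_nm = c(seq(280, 1702, by = 2),
                                                    seq(1705, 2600, by = 5)),
                                  water_scale = 0.192014,
                                  tail_scale = 3.536828) {
  wl <- wavelength_nm
  um <- wl / 1000
  airmass <- 1.5

  # Planck extraterrestrial curve, scaled to ~1250 W m-2 over 280-2600 nm
  h <- 6.62607015e-34; cc <- 2.99792458e8; kb <- 1.380649e-23; Tsun <- 5772
  lam <- wl * 1e-9
  planck <- lam^-5 / (exp(h * cc / (lam * kb * Tsun)) - 1)
  e0 <- planck / trapz(wl, planck) * 1250

  # molecular (Rayleigh) and aerosol optical depths
  tau_r <- 0.008735 * um^-4.08
  tau_a <- 0.084 * (um / 0.5)^-1.2
  # ozone: Hartley/Huggins UV edge plus a weak Chappuis dip
  tau_o3 <- 6 * exp(-(wl - 250) / 25) + 0.032 * exp(-((wl - 600)^2) / (2 * 80^2))
  # oxygen A-band and CO2 bands
  tau_gas <- 0.6 * exp(-((wl - 762)^2) / (2 * 5^2)) +
    0.3 * exp(-((wl - 2010)^2) / (2 * 30^2)) +
    0.15 * exp(-((wl - 1600)^2) / (2 * 25^2))
  # water-vapour bands (centre nm, depth, width nm)
  wv <- rbind(c(720, 0.35, 12), c(820, 0.30, 15), c(940, 1.00, 22),
              c(1130, 1.20, 28), c(1400, 6.00, 45), c(1870, 9.00, 55),
              c(2600, 12.00, 120))
  tau_w <- rep(0, length(wl))
  for (i in seq_len(nrow(wv))) {
    d <- wv[i, 2] * if (wv[i, 1] > 1700) tail_scale else water_scale
    tau_w <- tau_w + d * exp(-((wl - wv[i, 1])^2) / (2 * wv[i, 3]^2))
  }
  # weak NIR continuum beyond 1700 nm
  tau_w <- tau_w + ifelse(wl > 1700, 0.25 * tail_scale * (wl - 1700) / 900, 0)

  t_direct <- exp(-airmass * (tau_r + tau_a + tau_o3 + tau_gas + tau_w))
  direct <- e0 * t_direct
  # diffuse: roughly half the Rayleigh+aerosol-scattered light reaches the
  # tilted surface, attenuated by the absorbing species
  t_abs <- exp(-airmass * (tau_o3 + tau_gas + tau_w))
  diffuse <- 0.5 * e0 * (1 - exp(-airmass * (tau_r + 0.35 * tau_a))) * t_abs
  global <- direct + diffuse

  data.frame(wavelength_nm = wl,
             extraterrestrial = e0,
             global_tilt = global,
             direct_circumsolar = direct)
}

#' Load a reference solar irradiance spectrum
#'
#' By default loads the packaged synthetic reference table (see
#' [solar_reference_model()]) and returns the requested irradiance
#' variant. A custom file may be supplied: delimited text with a
#' wavelength column and either named irradiance columns matching the
#' reference layout or a single second column (variant `"custom"`).
#'
#' @param path path to a custom table, or `NULL` for the bundled one.
#' @param variant `"global-tilt"` (default), `"direct-circumsolar"` or
#'   `"extraterrestrial"`; ignored for two-column custom files.
#' @return An object of class `solar_spectrum` with fields
#'   `wavelength_nm`, `irradiance` (W m-2 nm-1) and `variant`.
#' @export
load_solar <- function(path = NULL, variant = c("global-tilt",
                                                "direct-circumsolar",
                                                "extraterrestrial")) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    path <- system.file("extdata", "solar_reference_synthetic.csv",
                        package = "shelltherm", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  if (ncol(tab) < 2L) st_stop("solar_column", "solar table needs >= 2 columns")
  wl_col <- grep("wave", names(tab), ignore.case = TRUE)[1]
  if (is.na(wl_col)) wl_col <- 1L
  if (ncol(tab) == 2L) {
    irr <- tab[[setdiff(seq_len(2L), wl_col)]]
    variant <- "custom"
  } else {
    col <- switch(variant,
                  "global-tilt" = "global_tilt",
                  "direct-circumsolar" = "direct_circumsolar",
                  "extraterrestrial" = "extraterrestrial")
    if (!col %in% names(tab))
      st_stop("solar_column", paste("missing irradiance column:", col))
    irr <- tab[[col]]
  }
  solar_spectrum(tab[[wl_col]], irr, variant)
}

#' Construct and validate a solar spectrum object
#'
#' @param wavelength_nm strictly increasing nm grid covering at least
#'   300--2600 nm with no gap wider than 5 nm.
#' @param irradiance spectral irradiance in W m-2 nm-1, non-negative.
#' @param variant label for the irradiance column used.
#' @return An object of class `solar_spectrum`.
#' @export
solar_spectrum <- function(wavelength_nm, irradiance, variant = "custom") {
  wl <- as.numeric(wavelength_nm); irr <- as.numeric(irradiance)
  o <- order(wl); wl <- wl[o]; irr <- irr[o]
  if (!is_strictly_increasing(wl))
    st_stop("solar_invalid", "solar wavelengths must be strictly increasing")
  if (any(!is.finite(irr)) || any(irr < 0))
    st_stop("solar_invalid", "irradiance must be finite and >= 0")
  if (min(wl) > 300 || max(wl) < 2600)
    st_stop("solar_coverage", "solar spectrum must cover [300, 2600] nm")
  keep <- wl >= 300 & wl <= 2600
  if (any(diff(wl[keep]) > 5 + 1e-9))
    st_stop("solar_coverage", "gap > 5 nm in solar coverage of [300, 2600]")
  structure(list(wavelength_nm = wl, irradiance = irr, variant = variant),
            class = "solar_spectrum")
}

#' @export
print.solar_spectrum <- function(x, ...) {
  cat(sprintf("<solar_spectrum> %s, %d points, %.0f-%.0f nm, total %.1f W/m2\n",
              x$variant, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm),
              trapz(x$wavelength_nm, x$irradiance)))
  invisible(x)
}

# integral of irradiance over [lo, hi], inserting exact endpoints
solar_band_integral <- function(solar, lo, hi) {
  wl <- solar$wavelength_nm; irr <- solar$irradiance
  if (lo < min(wl) || hi > max(wl))
    st_stop("solar_coverage", "band outside solar spectrum coverage")
  inner <- wl > lo & wl < hi
  x <- c(lo, wl[inner], hi)
  y <- stats::approx(wl, irr, xout = x)$y
  trapz(x, y)
}

#' Fraction of solar energy within a band
#'
#' Ratio of the trapezoid irradiance integral over `b` to the integral
#' over `reference`; `b` must be nested within `reference`.
#'
#' @param solar a [solar_spectrum()].
#' @param b the nested [band()].
#' @param reference the reference [band()].
#' @return A fraction in (0, 1].
#' @export
#' @examples
#' \dontrun{
#' sol <- load_solar()
#' band_energy_fraction(sol, band_uv(), band_total())  # ~0.503
#' }
band_energy_fraction <- function(solar, b, reference) {
  if (b$lo_nm < reference$lo_nm || b$hi_nm > reference$hi_nm)
    st_stop("band_nesting", "band must be nested within the reference band")
  solar_band_integral(solar, b$lo_nm, b$hi_nm) /
    solar_band_integral(solar, reference$lo_nm, reference$hi_nm)
}

#' Solar-weighted reflectivity of a spectrum over a band
#'
#' Reflectivity is the reflectance spectrum weighted by the solar
#' irradiance spectrum and normalised by the irradiance integral over the
#' band:
#' \deqn{R = \frac{\int S(\lambda) I(\lambda) d\lambda}
#'                {\int I(\lambda) d\lambda} \times 100}
#' Both curves are linearly interpolated onto a common 1 nm grid over the
#' band and integrated by the trapezoid rule.
#'
#' @param spec a [spectrum()] covering the band.
#' @param solar a [solar_spectrum()].
#' @param b a [band()].
#' @return Reflectivity in percent.
#' @export
solar_reflectivity <- function(spec, solar, b) {
  validate_spectrum(spec)
  if (min(spec$wavelength_nm) > b$lo_nm + 1e-9 ||
      max(spec$wavelength_nm) < b$hi_nm - 1e-9)
    st_stop("band_coverage",
            sprintf("spectrum [%.0f, %.0f] does not cover band [%.0f, %.0f]",
                    min(spec$wavelength_nm), max(spec$wavelength_nm),
                    b$lo_nm, b$hi_nm))
  grid <- seq(b$lo_nm, b$hi_nm, by = 1)
  if (grid[length(grid)] < b$hi_nm) grid <- c(grid, b$hi_nm)
  s <- stats::approx(spec$wavelength_nm, spec$reflectance, xout = grid)$y
  i <- stats::approx(solar$wavelength_nm, solar$irradiance, xout = grid)$y
  100 * trapz(grid, s * i) / trapz(grid, i)
}
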