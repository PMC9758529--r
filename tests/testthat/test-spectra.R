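test_that("read_spectrum detects units, sorts, skips headers and collapses duplicates", {
  # percent units detected and converted
  p1 <- write_spectrum_file(c(400, 500), c(50.0, 60.0))
  s1 <- read_spectrum(p1)
  expect_equal(s1$reflectance, c(0.50, 0.60))

  # rows sorted by wavelength
  p2 <- write_spectrum_file(c(500, 400), c(0.6, 0.5))
  s2 <- read_spectrum(p2)
  expect_equal(s2$wavelength_nm, c(400, 500))
  expect_equal(s2$reflectance, c(0.5, 0.6))

  # header skipped, values identical to headerless file
  p3 <- write_spectrum_file(c(400, 500), c(0.5, 0.6), header = TRUE)
  expect_equal(read_spectrum(p3)$reflectance, s2$reflectance)

  # whitespace delimiter accepted
  p4 <- write_spectrum_file(c(400, 500), c(0.5, 0.6), sep = " ")
  expect_equal(read_spectrum(p4)$reflectance, c(0.5, 0.6))

  # duplicate wavelengths collapsed by mean
  p5 <- write_spectrum_file(c(400, 400, 500), c(0.4, 0.6, 0.7))
  s5 <- read_spectrum(p5)
  expect_equal(s5$wavelength_nm, c(400, 500))
  expect_equal(s5$reflectance, c(0.5, 0.7))
})

test_that("read_spectrum errors name the offending line or condition", {
  bad <- tempfile()
  writeLines(c("400,0.5", "oops,xx", "500,0.6"), bad)
  expect_error(read_spectrum(bad), "line 2", class = "spectrum_parse")

  short <- write_spectrum_file(400, 0.5)
  expect_error(read_spectrum(short), class = "spectrum_empty")
})

test_that("filename convention parses into metadata", {
  m <- parse_spectrum_filename("snail07_apex_dry_nir.csv")
  expect_equal(m$specimen, "snail07")
  expect_equal(m$patch, "apex")
  expect_equal(m$state, "dry")
  expect_equal(m$instrument, "nir")
  expect_length(parse_spectrum_filename("random_name.csv"), 0)
})

test_that("splice joins the instrument ranges continuously", {
  wl_v <- seq(300, 1005, by = 5)
  wl_n <- seq(995, 1700, by = 5)

  # identical constants pass through unchanged
  sp <- splice(spectrum(wl_v, rep(0.4, length(wl_v))),
               spectrum(wl_n, rep(0.4, length(wl_n))))
  expect_true(all(abs(sp$reflectance - 0.4) < 1e-12))
  expect_equal(range(sp$wavelength_nm), c(300, 1700))
  expect_identical(sp$meta$instrument, "spliced")

  # multiplicative offset correction forces continuity
  sp2 <- splice(spectrum(wl_v, rep(0.40, length(wl_v))),
                spectrum(wl_n, rep(0.50, length(wl_n))))
  expect_true(all(abs(sp2$reflectance - 0.40) < 1e-12))

  # a continuous piecewise line is recovered with no step at the boundary
  line <- function(w) 0.2 + (w - 300) * (0.6 - 0.2) / (1700 - 300)
  sp3 <- splice(spectrum(wl_v, line(wl_v)), spectrum(wl_n, line(wl_n)))
  expect_lt(max(abs(sp3$reflectance - line(sp3$wavelength_nm))), 1e-9)
  j <- which(sp3$wavelength_nm >= 995 & sp3$wavelength_nm <= 1005)
  expect_lt(max(abs(diff(sp3$reflectance[j]) -
                      diff(line(sp3$wavelength_nm[j])))), 1e-9)
})

test_that("splice rejects a coverage gap at the boundary", {
  vis <- spectrum(seq(300, 990, 5), rep(0.4, 139))
  nir <- spectrum(seq(1000, 1700, 5), rep(0.4, 141))
  expect_error(splice(vis, nir), class = "splice_gap")
})

test_that("resample interpolates linearly and preserves endpoints", {
  s <- spectrum(c(400, 500), c(0.2, 0.4))
  r <- resample(s, 50)
  expect_equal(r$reflectance[r$wavelength_nm == 450], 0.3)
  expect_equal(range(r$wavelength_nm), c(400, 500))

  # resampling onto the spectrum's own grid is the identity
  s2 <- spectrum(seq(300, 400, 10), runif(11))
  expect_equal(resample(s2, 10)$reflectance, s2$reflectance)

  # dense-grid oracle: a quadratic sampled at 0.1 nm, queried at 1 nm
  wl_dense <- seq(400, 500, by = 0.1)
  quad <- function(w) 0.3 + 1e-5 * (w - 450)^2
  sd <- spectrum(wl_dense, quad(wl_dense))
  rd <- resample(sd, 1)
  expect_lt(max(abs(rd$reflectance - quad(rd$wavelength_nm))), 1e-4)

  expect_error(resample(s, grid = seq(300, 600, 10)), class = "resample_range")
})

test_that("smoothing reproduces constants and straight lines, reduces noise", {
  wl <- seq(300, 1700, by = 2)
  for (val in c(0.1, 0.3, 0.9)) {
    sm <- smooth_spectrum(constant_spectrum(val, wl))
    expect_lt(max(abs(sm$reflectance - val)), 1e-9)
  }

  line <- 0.2 + (wl - 300) / 7000
  sm <- smooth_spectrum(spectrum(wl, line))
  expect_lt(max(abs(sm$reflectance - line)), 1e-9)

  set.seed(11)
  noisy <- line + rnorm(length(wl), 0, 0.02)
  smn <- smooth_spectrum(spectrum(wl, noisy), span = 0.10)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(smn$reflectance - line), rms(noisy - line))

  expect_error(smooth_spectrum(spectrum(c(300, 400), c(0.1, 0.2))),
               class = "smooth_error")
})

test_that("negative smoothed values are clamped to zero with a warning", {
  # raw spectrometer noise can dip below zero near black surfaces
  wl <- seq(300, 500, by = 2)
  set.seed(2)
  vals <- -0.01 + rnorm(length(wl), 0, 0.005)
  expect_warning(sm <- smooth_spectrum(spectrum(wl, vals), span = 0.3),
                 class = "smooth_clamp")
  expect_true(all(sm$reflectance >= 0))
})

test_that("pipeline preserves constants and a strictly increasing grid", {
  for (val in c(0.05, 0.4, 1.1)) {
    wl_v <- seq(300, 1005, by = 3)
    wl_n <- seq(996, 1700, by = 3)
    out <- process_spectrum(spectrum(wl_v, rep(val, length(wl_v))),
                            spectrum(wl_n, rep(val, length(wl_n))))
    expect_lt(max(abs(out$reflectance - val)), 1e-8)
    expect_true(all(diff(out$wavelength_nm) > 0))
  }

  # random inputs: outputs keep strictly increasing grids
  set.seed(5)
  for (rep in 1:5) {
    wl_v <- sort(runif(80, 300, 1010)); wl_v <- wl_v[!duplicated(wl_v)]
    wl_v <- c(300, wl_v[wl_v > 300 & wl_v < 1010], 1010)
    wl_n <- sort(runif(80, 992, 1700)); wl_n <- wl_n[!duplicated(wl_n)]
    wl_n <- c(992, wl_n[wl_n > 992 & wl_n < 1700], 1700)
    vis <- spectrum(wl_v, runif(length(wl_v), 0.1, 0.6))
    nir <- spectrum(wl_n, runif(length(wl_n), 0.1, 0.6))
    out <- suppressWarnings(process_spectrum(vis, nir))
    expect_true(all(diff(out$wavelength_nm) > 0))
    expect_true(all(out$reflectance >= 0))
  }
})

test_that("smoothing and resampling commute on smooth inputs", {
  wl <- seq(300, 1700, by = 2)
  vals <- 0.3 + 0.1 * sin(wl / 300)
  s <- spectrum(wl, vals)
  a <- resample(smooth_spectrum(s, 0.1), 10)
  b <- smooth_spectrum(resample(s, 10), 0.1)
  common <- intersect(a$wavelength_nm, b$wavelength_nm)
  expect_lt(max(abs(a$reflectance[match(common, a$wavelength_nm)] -
                      b$reflectance[match(common, b$wavelength_nm)])), 1e-3)
})
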