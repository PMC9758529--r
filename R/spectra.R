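#' Reflectance spectra
#'
#' A `spectrum` object holds one reflectance curve on a strictly increasing
#' wavelength grid (nanometers), with reflectance stored as a unitless
#' fraction relative to a 99% white reflectance standard (0 = black,
#' 1 = standard; values slightly above 1 are possible for surfaces brighter
#' than the standard). Metadata records the specimen, species, colour patch,
#' shell state (wet or dry) and the instrument range the curve came from.
#'
#' @param wavelength_nm numeric vector of wavelengths in nm, strictly
#'   increasing, within 250--1800 nm.
#' @param reflectance numeric vector of reflectance fractions, same length.
#' @param meta named list with elements `specimen`, `species`, `patch`,
#'   `state` (`"wet"` or `"dry"`) and `instrument` (`"vis"`, `"nir"` or
#'   `"spliced"`). Missing elements are filled with `NA`.
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' s <- spectrum(400:700, rep(0.3, 301))
#' range(s$wavelength_nm)
spectrum <- function(wavelength_nm, reflectance, meta = list()) {
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance <- as.numeric(reflectance)
  defaults <- list(specimen = NA_character_, species = NA_character_,
                   patch = NA_character_, state = NA_character_,
                   instrument = NA_character_)
  meta <- utils::modifyList(defaults, as.list(meta))
  obj <- structure(list(wavelength_nm = wavelength_nm,
                        reflectance = reflectance,
                        meta = meta),
                   class = "spectrum")
  validate_spectrum(obj)
}

validate_spectrum <- function(s) {
  if (length(s$wavelength_nm) != length(s$reflectance))
    st_stop("spectrum_invalid", "wavelength and reflectance differ in length")
  if (length(s$wavelength_nm) < 2L)
    st_stop("spectrum_empty", "a spectrum needs at least two points")
  if (!is_strictly_increasing(s$wavelength_nm))
    st_stop("spectrum_invalid", "wavelengths must be strictly increasing")
  if (any(s$wavelength_nm < 250 | s$wavelength_nm > 1800))
    st_stop("spectrum_invalid", "wavelengths must lie within [250, 1800] nm")
  if (any(!is.finite(s$reflectance)))
    st_stop("spectrum_invalid", "reflectance values must be finite")
  s
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f-%.0f nm [%s]\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm),
              ifelse(is.na(x$meta$instrument), "?", x$meta$instrument)))
  cat(sprintf("  specimen=%s patch=%s state=%s\n", x$meta$specimen,
              x$meta$patch, x$meta$state))
  invisible(x)
}

#' Read a reflectance spectrum from delimited text
#'
#' Reads a two-column (wavelength nm, reflectance) comma- or
#' whitespace-delimited file as exported by spectrometer acquisition
#' software. A single non-numeric header line is skipped. Reflectance in
#' percent is auto-detected (maximum value > 1.5) and converted to
#' fraction. Rows are sorted by wavelength and duplicate wavelengths are
#' collapsed by their mean.
#'
#' @param path file path.
#' @param meta metadata list passed to [spectrum()]. When `NULL`, metadata
#'   is parsed from the file name via [parse_spectrum_filename()].
#' @return A [spectrum()] in fraction units.
#' @export
read_spectrum <- function(path, meta = NULL) {
  if (!file.exists(path)) st_stop("spectrum_io", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) st_stop("spectrum_empty", paste("empty file:", path))

  parse_line <- function(ln) {
    parts <- strsplit(trimws(ln), "[,\t ]+")[[1]]
    suppressWarnings(as.numeric(parts))
  }
  first <- parse_line(lines[1])
  start <- if (any(is.na(first)) || length(first) < 2L) 2L else 1L
  if (start > length(lines))
    st_stop("spectrum_empty", paste("fewer than 2 usable rows in", path))

  rows <- lapply(seq(start, length(lines)), function(i) {
    v <- parse_line(lines[i])
    if (length(v) < 2L || any(is.na(v[1:2])))
      st_stop("spectrum_parse",
              sprintf("non-numeric data on line %d of %s", i, path))
    v[1:2]
  })
  m <- do.call(rbind, rows)
  if (nrow(m) < 2L)
    st_stop("spectrum_empty", paste("fewer than 2 usable rows in", path))

  # collapse duplicate wavelengths by mean, then sort
  refl <- tapply(m[, 2], m[, 1], mean)
  wl <- as.numeric(names(refl))
  o <- order(wl)
  wl <- wl[o]
  refl <- as.numeric(refl)[o]
  if (max(refl) > 1.5) refl <- refl / 100

  if (is.null(meta)) meta <- parse_spectrum_filename(path)
  spectrum(wl, refl, meta)
}

#' Parse spectrum metadata from a file name
#'
#' Interprets file names of the form
#' `<specimen>_<patch>_<state>_<vis|nir>.<ext>`.
#' Unrecognised names yield all-`NA` metadata.
#'
#' @param path file path or name.
#' @return A metadata list suitable for [spectrum()].
#' @export
parse_spectrum_filename <- function(path) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  if (length(parts) >= 4L &&
      parts[length(parts)] %in% c("vis", "nir") &&
      parts[length(parts) - 1L] %in% c("wet", "dry")) {
    n <- length(parts)
    list(specimen = paste(parts[seq_len(n - 3L)], collapse = "_"),
         patch = parts[n - 2L], state = parts[n - 1L], instrument = parts[n])
  } else {
    list()
  }
}

#' Splice UV-visible and NIR instrument ranges into one spectrum
#'
#' Shell reflectance is acquired on two instruments covering roughly
#' 300--1000 nm and 1000--1700 nm. This joins the two curves at a boundary
#' wavelength: values below the boundary are taken from the UV-visible
#' curve and values at or above it from the NIR curve, after rescaling the
#' NIR segment by the ratio of mean reflectance in a +/-10 nm window around
#' the boundary so the joined curve is continuous (instrument step removal).
#'
#' @param vis spectrum covering wavelengths up to the boundary.
#' @param nir spectrum covering wavelengths from the boundary up.
#' @param boundary_nm splice wavelength, default 1000 nm.
#' @param window_nm half-width of the matching window, default 10 nm.
#' @return A spliced [spectrum()] tagged `instrument = "spliced"`.
#' @export
splice <- function(vis, nir, boundary_nm = 1000, window_nm = 10) {
  validate_spectrum(vis); validate_spectrum(nir)
  if (min(nir$wavelength_nm) - max(vis$wavelength_nm) > 5)
    st_stop("splice_gap",
            sprintf("coverage gap of %.1f nm at the splice boundary",
                    min(nir$wavelength_nm) - max(vis$wavelength_nm)))
  if (max(vis$wavelength_nm) < boundary_nm - 5 ||
      min(nir$wavelength_nm) > boundary_nm + 5)
    st_stop("splice_gap", "neither instrument reaches the splice boundary")

  # estimate the instrument step on the common support of the matching
  # window, interpolating both curves onto one grid so the comparison is
  # symmetric (a shared continuous curve then yields scale exactly 1)
  win_lo <- max(boundary_nm - window_nm, min(nir$wavelength_nm),
                min(vis$wavelength_nm))
  win_hi <- min(boundary_nm + window_nm, max(vis$wavelength_nm),
                max(nir$wavelength_nm))
  scale <- 1
  if (win_hi > win_lo) {
    grid <- seq(win_lo, win_hi, length.out = 21)
    mv <- mean(stats::approx(vis$wavelength_nm, vis$reflectance, grid)$y)
    mn <- mean(stats::approx(nir$wavelength_nm, nir$reflectance, grid)$y)
    if (is.finite(mv) && is.finite(mn) && mn > 0) scale <- mv / mn
  }

  keep_v <- vis$wavelength_nm < boundary_nm
  keep_n <- nir$wavelength_nm >= boundary_nm
  wl <- c(vis$wavelength_nm[keep_v], nir$wavelength_nm[keep_n])
  re <- c(vis$reflectance[keep_v], scale * nir$reflectance[keep_n])
  meta <- vis$meta
  meta$instrument <- "spliced"
  spectrum(wl, re, meta)
}

#' Resample a spectrum onto a regular wavelength grid
#'
#' Linear interpolation onto a regular grid with the given step. The grid
#' starts at the spectrum's first wavelength; the final measured endpoint
#' is appended if the regular grid does not land on it, so the measured
#' range is preserved exactly. No extrapolation is performed.
#'
#' @param spec a [spectrum()].
#' @param grid_step_nm grid step in nm, default 1.
#' @param grid optional explicit grid (overrides `grid_step_nm`); must lie
#'   within the measured range.
#' @return A resampled [spectrum()].
#' @export
resample <- function(spec, grid_step_nm = 1, grid = NULL) {
  validate_spectrum(spec)
  rng <- range(spec$wavelength_nm)
  if (is.null(grid)) {
    if (grid_step_nm <= 0) st_stop("resample_range", "grid step must be > 0")
    grid <- seq(rng[1], rng[2], by = grid_step_nm)
    if (grid[length(grid)] < rng[2]) grid <- c(grid, rng[2])
  }
  if (min(grid) < rng[1] - 1e-9 || max(grid) > rng[2] + 1e-9)
    st_stop("resample_range", "requested grid extends beyond the measured range")
  re <- stats::approx(spec$wavelength_nm, spec$reflectance, xout = grid,
                      method = "linear", rule = 1)$y
  spectrum(grid, re, spec$meta)
}

#' Smooth a spectrum with a locally weighted linear regression
#'
#' One pass of a local-linear smoother with tricube weights (loess,
#' degree 1), with the span given as the fraction of points in each local
#' window. Negative smoothed values are clamped to zero with a warning;
#' values above 1 are retained (reflectance is measured relative to a
#' white standard and may legitimately exceed it).
#'
#' @param spec a [spectrum()].
#' @param span fraction of points in the local window, default 0.10.
#' @return A smoothed [spectrum()] on the same grid.
#' @export
smooth_spectrum <- function(spec, span = 0.10) {
  validate_spectrum(spec)
  if (span <= 0 || span > 1) st_stop("smooth_error", "span must be in (0, 1]")
  n <- length(spec$wavelength_nm)
  if (n < 4L) st_stop("smooth_error", "too few points to smooth (need >= 4)")
  # loess requires enough points in the window for a degree-1 fit
  span_eff <- max(span, 4 / n)
  fit <- stats::loess(r ~ w,
                      data = data.frame(w = spec$wavelength_nm,
                                        r = spec$reflectance),
                      span = span_eff, degree = 1, family = "gaussian",
                      surface = "direct")
  re <- as.numeric(stats::predict(fit, newdata =
                                    data.frame(w = spec$wavelength_nm)))
  if (any(re < 0)) {
    st_warn("smooth_clamp",
            sprintf("%d smoothed reflectance values < 0 clamped to 0",
                    sum(re < 0)))
    re[re < 0] <- 0
  }
  spectrum(spec$wavelength_nm, re, spec$meta)
}

#' Process a raw instrument pair into an analysis-ready spectrum
#'
#' Convenience wrapper: splice the two instrument ranges, resample to a
#' regular grid and smooth. Smoothing is applied after splicing by
#' default; set `smooth_first = TRUE` to smooth each instrument range
#' before joining.
#'
#' @param vis,nir the two instrument spectra.
#' @param boundary_nm splice boundary, default 1000 nm.
#' @param grid_step_nm resampling step, default 1 nm.
#' @param span smoother span, default 0.10.
#' @param smooth_first smooth each range before splicing instead of after.
#' @return An analysis-ready [spectrum()].
#' @export
process_spectrum <- function(vis, nir, boundary_nm = 1000, grid_step_nm = 1,
                             span = 0.10, smooth_first = FALSE) {
  if (smooth_first) {
    vis <- smooth_spectrum(vis, span)
    nir <- smooth_spectrum(nir, span)
  }
  s <- resample(splice(vis, nir, boundary_nm), grid_step_nm)
  if (!smooth_first) s <- smooth_spectrum(s, span)
  s
}
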