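# shared fixtures built in code

# bundled solar spectrum, loaded once per test run
solar_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_solar()
    cache
  }
})

# write a two-column spectrum file, returns the path
write_spectrum_file <- function(wl, refl, path = tempfile(fileext = ".csv"),
                                header = FALSE, sep = ",") {
  lines <- paste(wl, refl, sep = sep)
  if (header) lines <- c(paste("wavelength", "reflectance", sep = sep), lines)
  writeLines(lines, path)
  path
}

# constant-reflectance spectrum across the full analysis range
constant_spectrum <- function(value, wl = seq(300, 1700, by = 2),
                              meta = list()) {
  spectrum(wl, rep(value, length(wl)), meta)
}

# small fixed ultrametric tree over n species named species_01..n
fixture_tree <- function(n = 4) {
  simulate_yule(n, 1, seed = 99, tip_labels = sprintf("species_%02d", 1:n))
}

# brute-force normal-equations OLS: returns intercept, slope, residuals
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2],
       residuals = as.numeric(y - X %*% beta))
}
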