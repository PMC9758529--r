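#' Configuration for the synthetic reflectivity study
#'
#' Defaults emulate the design of the shell-reflectivity study: 19
#' species on a simulated Yule tree, 3 individuals per species, each
#' measured wet and dry. Fixed effects for the total-reflectivity band
#' default to the published posterior means (intercept 13.11, habitat
#' exposed 9.04, state dry 3.71, interaction 7.44, percent), and the
#' UV-visible band to its published counterparts. Variance components
#' (5, 2 and 2 percentage points for species, individual and residual)
#' encode intraspecific variation substantially smaller than
#' interspecific variation. `band_cor` is the cross-band correlation of
#' the random components, calibrated so the squared correlation between
#' generated UV-visible and NIR reflectivity is ~0.52 at defaults.
#'
#' @param n_species,n_individuals study size.
#' @param n_exposed species assigned to the exposed microhabitat.
#' @param beta_total,beta_uv fixed effects (intercept, habitat, state,
#'   interaction) for the two generated bands.
#' @param sd_species,sd_individual,sd_residual variance components
#'   (percentage points), applied to both bands.
#' @param band_cor cross-band correlation of random components.
#' @param birth_rate Yule speciation rate for the simulated tree.
#' @return A config list.
#' @export
reflectivity_config <- function(n_species = 19, n_individuals = 3,
                                n_exposed = 10,
                                beta_total = c(13.11, 9.04, 3.71, 7.44),
                                beta_uv = c(9.56, 5.26, 2.71, 5.42),
                                sd_species = 5, sd_individual = 2,
                                sd_residual = 2, band_cor = 0.76,
                                birth_rate = 1) {
  cfg <- list(n_species = n_species, n_individuals = n_individuals,
              n_exposed = n_exposed, beta_total = beta_total,
              beta_uv = beta_uv, sd_species = sd_species,
              sd_individual = sd_individual, sd_residual = sd_residual,
              band_cor = band_cor, birth_rate = birth_rate)
  if (n_species < 2 || n_individuals < 1 || n_exposed < 1 ||
      n_exposed >= n_species)
    st_stop("config_invalid", "invalid study sizes")
  if (length(beta_total) != 4L || length(beta_uv) != 4L)
    st_stop("config_invalid", "fixed-effect vectors must have length 4")
  if (any(c(sd_species, sd_individual, sd_residual) < 0) ||
      abs(band_cor) > 1)
    st_stop("config_invalid", "invalid variance components")
  cfg
}

# two vectors with marginal sd `sd` and cross correlation rho; `draw`
# generates one vector of unit-variance noise (possibly correlated via A)
correlated_pair <- function(draw, sd, rho) {
  z1 <- draw(); z2 <- draw()
  list(a = sd * z1, b = sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Generate a synthetic reflectivity study
#'
#' Simulates a Yule species tree, assigns microhabitat at species level,
#' and draws per-record total and UV-visible reflectivity from the
#' phylogenetic mixed model `y = X beta + species effect (MVN, sd^2 A) +
#' individual effect + residual`, with the two bands' random components
#' correlated by `band_cor`. NIR reflectivity is derived from the exact
#' energy-weighted mixture identity `R_total = (E_uv R_uv + E_nir R_nir)
#' / (E_uv + E_nir)` using the bundled solar spectrum, so every record
#' satisfies the band identity by construction.
#'
#' @param config a [reflectivity_config()].
#' @param seed integer seed (tree and data).
#' @param solar a [solar_spectrum()] for the band energy weights;
#'   default loads the bundled table.
#' @return A list with `records` (data.frame as in
#'   [build_reflectivity_table()]), `tree`, and `truth` (all generating
#'   values and seeds).
#' @export
gen_reflectivity_study <- function(config = reflectivity_config(), seed,
                                   solar = NULL) {
  if (missing(seed)) st_stop("seed_required", "an explicit seed is required")
  if (is.null(solar)) solar <- load_solar()
  w_uv <- band_energy_fraction(solar, band_uv(), band_total())
  w_nir <- 1 - w_uv

  species <- sprintf("species_%02d", seq_len(config$n_species))
  tree <- simulate_yule(config$n_species, config$birth_rate, seed = seed,
                        tip_labels = species)
  A <- phylo_correlation(tree, species = species)
  L <- t(chol(A + diag(1e-10, nrow(A))))

  habitat <- rep("sheltered", config$n_species)
  habitat[sample.int(config$n_species, config$n_exposed)] <- "exposed"

  n_ind <- config$n_species * config$n_individuals
  df <- expand.grid(ind = seq_len(config$n_individuals),
                    species = species, state = c("wet", "dry"),
                    stringsAsFactors = FALSE)
  df$specimen <- sprintf("%s_i%d", df$species, df$ind)
  df$habitat <- habitat[match(df$species, species)]
  X <- cbind(1, (df$habitat == "exposed") * 1, (df$state == "dry") * 1,
             (df$habitat == "exposed") * (df$state == "dry") * 1)

  sp_eff <- correlated_pair(function() as.numeric(L %*% stats::rnorm(config$n_species)),
                            config$sd_species, config$band_cor)
  ind_eff <- correlated_pair(function() stats::rnorm(n_ind),
                             config$sd_individual, config$band_cor)
  res_eff <- correlated_pair(function() stats::rnorm(nrow(df)),
                             config$sd_residual, config$band_cor)
  s_i <- match(df$species, species)
  ind_ids <- unique(df$specimen)
  i_i <- match(df$specimen, ind_ids)

  r_total <- as.numeric(X %*% config$beta_total) +
    sp_eff$a[s_i] + ind_eff$a[i_i] + res_eff$a
  r_uv <- as.numeric(X %*% config$beta_uv) +
    sp_eff$b[s_i] + ind_eff$b[i_i] + res_eff$b
  r_nir <- (r_total - w_uv * r_uv) / w_nir

  records <- data.frame(specimen = df$specimen, species = df$species,
                        habitat = df$habitat, state = df$state,
                        R_total = r_total, R_uv = r_uv, R_nir = r_nir)
  records <- records[order(records$specimen, records$state), ]
  rownames(records) <- NULL
  truth <- list(beta_total = config$beta_total, beta_uv = config$beta_uv,
                sd_species = config$sd_species,
                sd_individual = config$sd_individual,
                sd_residual = config$sd_residual,
                band_cor = config$band_cor, w_uv = w_uv,
                habitat = stats::setNames(habitat, species), seed = seed)
  list(records = records, tree = tree, truth = truth)
}

#' Generate a smooth spectrum hitting target band reflectivities
#'
#' Builds a smooth reflectance curve (a logistic step centred near
#' 700 nm plus low-amplitude seeded sinusoidal bumps) and iteratively
#' rescales the UV-visible and NIR sides so that its solar-weighted
#' reflectivities reproduce the requested targets within 0.1 percentage
#' points (verified by re-integration).
#'
#' @param target_r_uv,target_r_nir target band reflectivities (percent,
#'   0--100).
#' @param solar a [solar_spectrum()]; default bundled.
#' @param seed integer seed for the bump pattern.
#' @return A [spectrum()] on 300--1700 nm.
#' @export
gen_spectrum <- function(target_r_uv, target_r_nir, solar = NULL, seed = 1) {
  if (target_r_uv < 0 || target_r_uv > 100 ||
      target_r_nir < 0 || target_r_nir > 100)
    st_stop("target_invalid", "targets must lie in [0, 100] percent")
  if (is.null(solar)) solar <- load_solar()
  set.seed(seed)
  wl <- seq(300, 1700, by = 2)
  step <- 1 / (1 + exp(-(wl - 700) / 25))
  bump <- rep(0, length(wl))
  for (k in 1:4) {
    bump <- bump + stats::runif(1, 0.2, 1) *
      sin(2 * pi * wl / stats::runif(1, 300, 900) + stats::runif(1, 0, 2 * pi))
  }
  bump <- bump / max(abs(bump), 1)
  base_uv <- max(target_r_uv, 0.5) / 100
  base_nir <- max(target_r_nir, 0.5) / 100
  s <- (base_uv + (base_nir - base_uv) * step) * (1 + 0.05 * bump)
  s <- pmax(s, 1e-6)

  blend <- step
  for (it in 1:30) {
    spec <- spectrum(wl, s, list(instrument = "spliced"))
    r_uv <- solar_reflectivity(spec, solar, band_uv())
    r_nir <- solar_reflectivity(spec, solar, band_nir())
    if (abs(r_uv - target_r_uv) < 0.05 && abs(r_nir - target_r_nir) < 0.05)
      break
    f_uv <- if (r_uv > 0) target_r_uv / r_uv else 1
    f_nir <- if (r_nir > 0) target_r_nir / r_nir else 1
    s <- pmax(s * (f_uv + (f_nir - f_uv) * blend), 0)
  }
  spec <- spectrum(wl, s, list(instrument = "spliced"))
  if (abs(solar_reflectivity(spec, solar, band_uv()) - target_r_uv) > 0.1 ||
      abs(solar_reflectivity(spec, solar, band_nir()) - target_r_nir) > 0.1)
    st_stop("target_unreachable",
            "could not reach the requested band reflectivities")
  spec
}

#' Configuration for the synthetic heating experiment
#'
#' Defaults emulate the field heating-rate experiment: 11 species with
#' per-species sample sizes (2, 5, 9, 9, 10, 10, 10, 10, 10, 10, 10) =
#' 95 individuals, each measured wet and dry; exposure times uniform on
#' 135--195 s; nearby rock temperature Normal(30, 1.2) deg C; species
#' total reflectivities spread over ~10--50%. Generating effects are the
#' published posterior means (reflectivity slope -0.02 deg C min-1 per
#' percent, wet state -0.46, shell length -0.02 per mm, reflectivity x
#' wet interaction 0). The rock-conduction slope (0.15 deg C min-1 per
#' deg C) and the variance components are package defaults documented in
#' the methods vignette.
#'
#' @param n_per_species individuals per species.
#' @param beta named generating effects.
#' @param rock_slope conductive heat-gain slope.
#' @param baseline_rate mean dry heating rate at the reference rock
#'   temperature before covariate effects.
#' @param rock_mean,rock_sd rock temperature distribution (deg C).
#' @param elapsed_range exposure time range (s).
#' @param refl_range species total-reflectivity range (percent).
#' @param sd_species,sd_individual,sd_residual variance components
#'   (deg C min-1).
#' @param birth_rate Yule speciation rate.
#' @return A config list.
#' @export
heating_config <- function(n_per_species = c(2, 5, 9, 9, 10, 10, 10, 10,
                                             10, 10, 10),
                           beta = c(reflectivity = -0.02, wet = -0.46,
                                    length = -0.02, refl_wet = 0),
                           rock_slope = 0.15, baseline_rate = 2.5,
                           rock_mean = 30, rock_sd = 1.2,
                           elapsed_range = c(135, 195),
                           refl_range = c(10, 50),
                           sd_species = 0.15, sd_individual = 0.10,
                           sd_residual = 0.20, birth_rate = 1) {
  if (any(n_per_species < 1) || length(n_per_species) < 2)
    st_stop("config_invalid", "need >= 2 species with >= 1 individual each")
  if (any(c(sd_species, sd_individual, sd_residual) < 0))
    st_stop("config_invalid", "variance components must be >= 0")
  if (diff(elapsed_range) < 0 || elapsed_range[1] <= 0)
    st_stop("config_invalid", "invalid elapsed range")
  list(n_per_species = n_per_species, beta = beta, rock_slope = rock_slope,
       baseline_rate = baseline_rate, rock_mean = rock_mean,
       rock_sd = rock_sd, elapsed_range = elapsed_range,
       refl_range = refl_range, sd_species = sd_species,
       sd_individual = sd_individual, sd_residual = sd_residual,
       birth_rate = birth_rate)
}

#' Generate a synthetic heating experiment
#'
#' Simulates a Yule tree over the heating-study species, assigns
#' species-level total reflectivity and individual shell lengths, and
#' builds heating rates as a rock-conduction term plus the configured
#' covariate effects plus phylogenetic species, individual and residual
#' noise. End temperatures are back-computed from the rate, the start
#' temperature and the elapsed time, so reading the records back through
#' [heating_rate()] reproduces the generated rates exactly.
#'
#' @param config a [heating_config()].
#' @param seed integer seed.
#' @return A list with `records` (heating CSV layout), `tree` and
#'   `truth`.
#' @export
gen_heating_study <- function(config = heating_config(), seed) {
  if (missing(seed)) st_stop("seed_required", "an explicit seed is required")
  n_sp <- length(config$n_per_species)
  species <- sprintf("species_%02d", seq_len(n_sp))
  tree <- simulate_yule(n_sp, config$birth_rate, seed = seed,
                        tip_labels = species)
  A <- phylo_correlation(tree, species = species)
  L <- t(chol(A + diag(1e-10, n_sp)))

  refl_sp <- sample(seq(config$refl_range[1], config$refl_range[2],
                        length.out = n_sp))
  len_sp <- stats::runif(n_sp, 10, 35)
  u <- config$sd_species * as.numeric(L %*% stats::rnorm(n_sp))

  rows <- list()
  for (s in seq_len(n_sp)) {
    for (i in seq_len(config$n_per_species[s])) {
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = sprintf("%s_i%02d", species[s], i),
        species = species[s],
        shell_length_mm = max(5, stats::rnorm(1, len_sp[s], 3)),
        r_total = refl_sp[s])
    }
  }
  ind <- do.call(rbind, rows)
  n_ind <- nrow(ind)
  v <- stats::rnorm(n_ind, 0, config$sd_individual)

  df <- rbind(transform(ind, state = "dry"), transform(ind, state = "wet"))
  df <- df[order(df$specimen, df$state), ]
  rownames(df) <- NULL
  i_i <- match(df$specimen, ind$specimen)
  s_i <- match(df$species, species)

  df$elapsed_s <- stats::runif(nrow(df), config$elapsed_range[1],
                               config$elapsed_range[2])
  df$rock_t_c <- stats::rnorm(nrow(df), config$rock_mean, config$rock_sd)
  wet <- (df$state == "wet") * 1
  b <- config$beta
  rate <- config$baseline_rate +
    config$rock_slope * (df$rock_t_c - config$rock_mean) +
    b[["reflectivity"]] * df$r_total + b[["length"]] * df$shell_length_mm +
    b[["wet"]] * wet + b[["refl_wet"]] * df$r_total * wet +
    u[s_i] + v[i_i] + stats::rnorm(nrow(df), 0, config$sd_residual)
  df$t_start_c <- stats::rnorm(nrow(df), 26, 1.5)
  df$t_end_c <- df$t_start_c + rate * df$elapsed_s / 60

  records <- df[, c("specimen", "species", "state", "shell_length_mm",
                    "t_start_c", "t_end_c", "elapsed_s", "rock_t_c",
                    "r_total")]
  truth <- list(beta = b, rock_slope = config$rock_slope,
                baseline_rate = config$baseline_rate,
                sd_species = config$sd_species,
                sd_individual = config$sd_individual,
                sd_residual = config$sd_residual,
                reflectivity = stats::setNames(refl_sp, species),
                seed = seed)
  list(records = records, tree = tree, truth = truth)
}
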