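#' Read a pipeline run configuration
#'
#' Flat YAML key-value file; unknown keys are rejected, missing keys take
#' the defaults below. All randomness flows from the two named seeds.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list overriding file values (e.g. from CLI
#'   flags).
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    spectra_dir = NULL, metadata_csv = NULL, tree_file = NULL,
    reflectivity_csv = NULL, heating_csv = NULL, out_dir = ".",
    band_edges = c(300, 700, 1700), smoothing_span = 0.10,
    smooth_first = FALSE, solar_variant = "global-tilt", solar_file = NULL,
    chains = 2, iterations = 6000, burn_in = 2000,
    tree_seed = 1, data_seed = 1,
    nir_variant = "covariate", rock_per_state = FALSE,
    log_level = "info")
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(defaults))
    if (length(unknown))
      st_stop("config_invalid",
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  for (key in c("spectra_dir", "metadata_csv", "tree_file",
                "reflectivity_csv", "heating_csv", "solar_file")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      st_stop("config_path", paste("declared path does not exist:",
                                   key, "=", cfg[[key]]))
  }
  if (!is.numeric(cfg$tree_seed) || !is.numeric(cfg$data_seed))
    st_stop("config_invalid", "seeds must be explicit integers")
  structure(cfg, class = "run_config")
}

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Simulate a study and write its files
#'
#' Writes the simulated records CSV, the species tree in newick, and a
#' `truth.json` holding every generating value, into `out_dir`.
#'
#' @param type `"reflectivity"` or `"heating"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param config optional [reflectivity_config()] / [heating_config()].
#' @return Invisibly, the list returned by the generator.
#' @export
run_simulate <- function(type = c("reflectivity", "heating"), out_dir,
                         seed, config = NULL) {
  type <- match.arg(type)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- if (type == "reflectivity") {
    gen_reflectivity_study(config %||% reflectivity_config(), seed = seed)
  } else {
    gen_heating_study(config %||% heating_config(), seed = seed)
  }
  csv <- file.path(out_dir, paste0(type, ".csv"))
  utils::write.csv(sim$records, csv, row.names = FALSE, quote = FALSE)
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  truth <- lapply(sim$truth, function(x) {
    if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
  })
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Run the spectra-to-reflectivity stage
#'
#' Reads every vis/nir spectrum pair listed in the metadata CSV (columns
#' `specimen,species,habitat,patch,state,instrument,path`) or discovered
#' in `spectra_dir` by the `<specimen>_<patch>_<state>_<vis|nir>.csv`
#' naming convention, splices, resamples and smooths each pair, computes
#' band reflectivities against the configured solar spectrum, and writes
#' the reflectivity table CSV. Per-file failures are logged and skipped;
#' more than 10% failures aborts the run.
#'
#' @param cfg a [run_config()] with `spectra_dir` and `metadata_csv`
#'   set.
#' @param out output CSV path; default `reflectivity.csv` in
#'   `cfg$out_dir`.
#' @return The reflectivity table, invisibly.
#' @export
run_reflectivity <- function(cfg, out = NULL) {
  if (is.null(cfg$spectra_dir) || is.null(cfg$metadata_csv))
    st_stop("config_path", "spectra_dir and metadata_csv are required")
  meta <- utils::read.csv(cfg$metadata_csv, stringsAsFactors = FALSE)
  solar <- load_solar(cfg$solar_file, variant = cfg$solar_variant)

  if ("path" %in% names(meta)) {
    files <- file.path(cfg$spectra_dir, meta$path)
    info <- meta
  } else {
    files <- list.files(cfg$spectra_dir, pattern = "\\.(csv|txt)$",
                        full.names = TRUE)
    parsed <- lapply(files, parse_spectrum_filename)
    keep <- vapply(parsed, function(p) length(p) > 0, TRUE)
    files <- files[keep]
    info <- do.call(rbind, lapply(parsed[keep], as.data.frame))
  }
  key <- function(d) paste(d$specimen, d$patch, d$state, sep = "|")
  ks <- unique(key(info))
  spectra <- list(); failed <- 0L
  for (k in ks) {
    i <- which(key(info) == k)
    iv <- i[info$instrument[i] == "vis"][1]
    ir <- i[info$instrument[i] == "nir"][1]
    res <- tryCatch({
      if (is.na(iv) || is.na(ir)) stop("missing vis or nir file")
      m <- as.list(info[iv, setdiff(names(info), c("instrument", "path"))])
      vis <- read_spectrum(files[iv], meta = c(m, instrument = "vis"))
      nir <- read_spectrum(files[ir], meta = c(m, instrument = "nir"))
      withCallingHandlers(
        process_spectrum(vis, nir, span = cfg$smoothing_span,
                         smooth_first = cfg$smooth_first),
        shelltherm_warning = function(w) {
          log_msg(cfg, "warn", k, ": ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      log_msg(cfg, "warn", "skipping ", k, ": ", conditionMessage(res))
    } else {
      spectra[[k]] <- res
    }
  }
  if (failed > 0.1 * length(ks))
    st_stop("pipeline_failures",
            sprintf("%d of %d spectrum pairs failed", failed, length(ks)))
  sp_meta <- unique(meta[c("specimen", "species", "habitat")])
  tab <- build_reflectivity_table(spectra, solar, sp_meta)
  for (i in seq_len(nrow(tab)))
    log_msg(cfg, "debug", sprintf("%s %s: total=%.2f uv=%.2f nir=%.2f",
                                  tab$specimen[i], tab$state[i],
                                  tab$R_total[i], tab$R_uv[i], tab$R_nir[i]))
  out <- out %||% file.path(cfg$out_dir, "reflectivity.csv")
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_reflectivity_csv(tab, out)
  log_msg(cfg, "info", "wrote ", out, " (", nrow(tab), " records)")
  invisible(tab)
}

#' Fit one of the four study models and write its outputs
#'
#' Fits the requested model (`total`, `uvvis` or `nir` reflectivity, or
#' `heating`) with the configured chain settings, and writes a
#' Table-style summary CSV (`parameter,estimate,ci_low,ci_high,ess,`
#' `rhat`), a draws CSV (one column per parameter plus a chain id), and
#' a JSON run record with the seeds and settings. A convergence failure
#' (any split R-hat > 1.1) completes with a warning status recorded in
#' the run record.
#'
#' @param cfg a [run_config()]; needs `reflectivity_csv` (or
#'   `heating_csv`) and `tree_file`.
#' @param which `"total"`, `"uvvis"`, `"nir"` or `"heating"`.
#' @param out_dir output directory; default `cfg$out_dir`.
#' @return The summary data.frame, invisibly.
#' @export
run_fit <- function(cfg, which = c("total", "uvvis", "nir", "heating"),
                    out_dir = NULL) {
  which <- match.arg(which)
  if (is.null(cfg$tree_file)) st_stop("config_path", "tree_file is required")
  tree <- read_newick(cfg$tree_file, file = TRUE)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warn_status <- FALSE
  fit <- withCallingHandlers({
    if (which == "heating") {
      if (is.null(cfg$heating_csv))
        st_stop("config_path", "heating_csv is required")
      records <- read_heating_csv(cfg$heating_csv)
      fit_heating_model(records, tree, seed = cfg$data_seed,
                        per_state = cfg$rock_per_state, chains = cfg$chains,
                        iterations = cfg$iterations, burn_in = cfg$burn_in)
    } else {
      if (is.null(cfg$reflectivity_csv))
        st_stop("config_path", "reflectivity_csv is required")
      records <- read_reflectivity_csv(cfg$reflectivity_csv)
      fit_reflectivity_model(records, tree, band = which,
                             nir_variant = cfg$nir_variant,
                             seed = cfg$data_seed, chains = cfg$chains,
                             iterations = cfg$iterations,
                             burn_in = cfg$burn_in)
    }
  }, shelltherm_warning = function(w) {
    warn_status <<- TRUE
    log_msg(cfg, "warn", conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  summary_csv <- file.path(out_dir, paste0("summary_", which, ".csv"))
  out <- fit$summary
  for (cl in c("estimate", "ci_low", "ci_high"))
    out[[cl]] <- round(out[[cl]], 4)
  out$ess <- round(out$ess)
  out$rhat <- round(out$rhat, 4)
  utils::write.csv(out, summary_csv, row.names = FALSE, quote = TRUE)

  draws <- do.call(rbind, lapply(seq_along(fit$posterior$draws), function(c)
    cbind(chain = c, as.data.frame(fit$posterior$draws[[c]]))))
  utils::write.csv(draws, file.path(out_dir, paste0("draws_", which, ".csv")),
                   row.names = FALSE, quote = FALSE)

  run_rec <- list(model = which, chains = cfg$chains,
                  iterations = cfg$iterations, burn_in = cfg$burn_in,
                  tree_seed = cfg$tree_seed, data_seed = cfg$data_seed,
                  nir_variant = cfg$nir_variant,
                  convergence_warning = warn_status)
  jsonlite::write_json(run_rec,
                       file.path(out_dir, paste0("run_", which, ".json")),
                       auto_unbox = TRUE)
  log_msg(cfg, "info", "wrote ", summary_csv,
          if (warn_status) " (with convergence warning)" else "")
  invisible(fit$summary)
}

#' Collate fitted models into a plain-text report
#'
#' Gathers every `summary_*.csv` in a run directory into one report,
#' together with the solar band energy fractions of the bundled
#' reference spectrum and, when the total-reflectivity model is present,
#' the model-implied group means (e.g. the exposed-dry mean as the sum
#' of the intercept, habitat, state and interaction estimates).
#'
#' @param run_dir directory holding [run_fit()] outputs.
#' @param out report file path; default `report.txt` in `run_dir`.
#' @return The report lines, invisibly.
#' @export
run_report <- function(run_dir, out = NULL) {
  files <- list.files(run_dir, pattern = "^summary_.*\\.csv$",
                      full.names = TRUE)
  if (!length(files)) st_stop("report_empty", "nothing to report")
  lines <- c("shelltherm run report", strrep("=", 60))

  solar <- load_solar()
  f_uv <- band_energy_fraction(solar, band_uv(), band_total())
  f_cov <- band_energy_fraction(solar, band_total(), band_solar())
  lines <- c(lines, "",
             sprintf("Solar reference: UV-visible share of 300-1700 nm = %.1f%%",
                     100 * f_uv),
             sprintf("                 NIR share of 300-1700 nm        = %.1f%%",
                     100 * (1 - f_uv)),
             sprintf("                 300-1700 nm share of 300-2600 nm = %.1f%%",
                     100 * f_cov))

  for (f in files) {
    tab <- utils::read.csv(f)
    model <- sub("^summary_(.*)\\.csv$", "\\1", basename(f))
    lines <- c(lines, "", sprintf("Model: %s", model), strrep("-", 60),
               utils::capture.output(print(tab, row.names = FALSE)))
    if (model == "total") {
      est <- stats::setNames(tab$estimate, tab$parameter)
      grp <- c("Intercept", "Habitat (Exposed)", "State (Dry)",
               "Habitat (Exposed):State (Dry)")
      if (all(grp %in% names(est))) {
        lines <- c(lines,
                   sprintf("Implied sheltered-dry mean: %.2f%%",
                           sum(est[grp[c(1, 3)]])),
                   sprintf("Implied exposed-dry mean:   %.2f%%",
                           sum(est[grp])))
      }
    }
    run_json <- file.path(run_dir, paste0("run_", model, ".json"))
    if (file.exists(run_json)) {
      rec <- jsonlite::read_json(run_json)
      if (isTRUE(rec$convergence_warning))
        lines <- c(lines, "WARNING: convergence warning recorded for this fit")
    }
  }
  out <- out %||% file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(lines)
}
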