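#' Average reflectivity over colour patches
#'
#' Shells with colour patterns are measured once per colour patch; since
#' patches cover approximately equal areas, the shell value is the
#' unweighted arithmetic mean of the patch reflectivities.
#'
#' @param values numeric vector of patch reflectivities (percent), length
#'   >= 1.
#' @return Mean reflectivity in percent.
#' @export
patch_average <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    st_stop("patch_empty", "patch_average needs >= 1 finite value")
  mean(values)
}

#' Build the per-specimen reflectivity table
#'
#' Computes solar-weighted reflectivity in the total (300--1700 nm),
#' UV-visible (300--700 nm) and NIR (700--1700 nm) bands for every
#' spectrum, then averages colour patches within specimen x state, giving
#' one record per specimen and shell state. Species and habitat come from
#' the metadata table.
#'
#' @param spectra list of analysis-ready [spectrum()] objects (spliced,
#'   covering 300--1700 nm) with `specimen`, `patch` and `state` metadata.
#' @param solar a [solar_spectrum()].
#' @param metadata data.frame with columns `specimen`, `species`,
#'   `habitat` (`exposed`/`sheltered`); one row per specimen.
#' @return data.frame with columns `specimen`, `species`, `habitat`,
#'   `state`, `R_total`, `R_uv`, `R_nir` (percent).
#' @export
build_reflectivity_table <- function(spectra, solar, metadata) {
  metadata <- as.data.frame(metadata)
  need <- c("specimen", "species", "habitat")
  if (!all(need %in% names(metadata)))
    st_stop("metadata_columns",
            paste("metadata must have columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(metadata$habitat), c("exposed", "sheltered"))
  if (length(bad))
    st_stop("habitat_unknown", paste("unknown habitat:", bad[1]))

  per_spec <- lapply(spectra, function(s) {
    data.frame(specimen = s$meta$specimen, state = s$meta$state,
               R_total = solar_reflectivity(s, solar, band_total()),
               R_uv = solar_reflectivity(s, solar, band_uv()),
               R_nir = solar_reflectivity(s, solar, band_nir()))
  })
  tab <- do.call(rbind, per_spec)
  agg <- stats::aggregate(tab[c("R_total", "R_uv", "R_nir")],
                          by = tab[c("specimen", "state")],
                          FUN = patch_average)

  specs <- unique(agg$specimen)
  missing_state <- specs[!vapply(specs, function(sp)
    all(c("wet", "dry") %in% agg$state[agg$specimen == sp]), TRUE)]
  if (length(missing_state))
    st_warn("missing_state",
            paste("specimens missing a shell state:",
                  paste(missing_state, collapse = ", ")))

  m <- match(agg$specimen, metadata$specimen)
  if (anyNA(m))
    st_stop("metadata_columns",
            paste("no metadata for specimen:", agg$specimen[which(is.na(m))[1]]))
  out <- data.frame(specimen = agg$specimen,
                    species = metadata$species[m],
                    habitat = metadata$habitat[m],
                    state = agg$state,
                    R_total = agg$R_total, R_uv = agg$R_uv,
                    R_nir = agg$R_nir)
  out[order(out$specimen, out$state), , drop = FALSE]
}

#' Residualize NIR reflectivity on UV-visible reflectivity
#'
#' Ordinary least-squares regression of NIR reflectivity on UV-visible
#' reflectivity; the residuals capture NIR variation independent of
#' UV-visible variation (the alternative to entering UV-visible as a
#' model covariate).
#'
#' @param records data.frame with columns `R_nir` and `R_uv`, >= 3 rows.
#' @return A list with `residuals` (per record, percentage points),
#'   `fitted`, `slope`, `intercept` and `r_squared`.
#' @export
uv_nir_residuals <- function(records) {
  records <- as.data.frame(records)
  ok <- is.finite(records$R_nir) & is.finite(records$R_uv)
  if (sum(ok) < 3L)
    st_stop("residual_few", "need >= 3 records with both bands")
  if (stats::var(records$R_uv[ok]) == 0)
    st_stop("residual_degenerate", "zero variance in UV-visible reflectivity")
  fit <- stats::lm(R_nir ~ R_uv, data = records[ok, ])
  res <- rep(NA_real_, nrow(records))
  fitv <- rep(NA_real_, nrow(records))
  res[ok] <- stats::residuals(fit)
  fitv[ok] <- stats::fitted(fit)
  list(residuals = res, fitted = fitv,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Write / read a reflectivity table CSV
#'
#' Columns `specimen,species,habitat,state,R_total,R_uv,R_nir` with
#' reflectivities in percent rounded to 4 decimals.
#'
#' @param tab a reflectivity table ([build_reflectivity_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_reflectivity_csv <- function(tab, path) {
  out <- tab
  for (cl in c("R_total", "R_uv", "R_nir")) out[[cl]] <- round(out[[cl]], 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reflectivity_csv
#' @export
read_reflectivity_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
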