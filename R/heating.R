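#' Heating rate from paired shell temperatures
#'
#' Difference between mean shell surface temperature at the end and
#' beginning of sun exposure, divided by the elapsed time in minutes.
#'
#' @param t_start_c,t_end_c mean shell surface temperatures (deg C).
#' @param elapsed_s elapsed time between the two thermal images (s), > 0.
#' @return Heating rate in deg C per minute (vectorised).
#' @export
#' @examples
#' heating_rate(25, 29, 120)  # 2 deg C / min
heating_rate <- function(t_start_c, t_end_c, elapsed_s) {
  if (any(elapsed_s <= 0)) st_stop("elapsed_invalid", "elapsed_s must be > 0")
  (t_end_c - t_start_c) / (elapsed_s / 60)
}

#' Residualize heating rate on nearby rock temperature
#'
#' Removes conductive heat-gain variation by regressing heating rate on
#' the mean temperature of the rock adjacent to each snail (OLS) and
#' returning the residuals. The regression is fit on all records pooled
#' across shell states by default; `per_state = TRUE` fits it within each
#' state.
#'
#' @param records data.frame with columns `t_start_c`, `t_end_c`,
#'   `elapsed_s`, `rock_t_c` (and `state` if `per_state`); >= 3 rows.
#' @param per_state fit the rock regression separately per shell state.
#' @return The input data.frame with added columns `rate` (deg C/min),
#'   `rate_fitted` and `rate_residual`; attributes `slope` and
#'   `intercept` hold the pooled regression coefficients.
#' @export
rock_residualize <- function(records, per_state = FALSE) {
  records <- as.data.frame(records)
  records$rate <- heating_rate(records$t_start_c, records$t_end_c,
                               records$elapsed_s)
  fit_one <- function(df) {
    if (nrow(df) < 3L) st_stop("residual_few", "need >= 3 records")
    if (stats::var(df$rock_t_c) == 0)
      st_stop("residual_degenerate", "rock temperature is constant")
    stats::lm(rate ~ rock_t_c, data = df)
  }
  if (per_state) {
    records$rate_fitted <- NA_real_
    records$rate_residual <- NA_real_
    for (st in unique(records$state)) {
      i <- records$state == st
      fit <- fit_one(records[i, ])
      records$rate_fitted[i] <- stats::fitted(fit)
      records$rate_residual[i] <- stats::residuals(fit)
    }
    attr(records, "slope") <- NA_real_
    attr(records, "intercept") <- NA_real_
  } else {
    fit <- fit_one(records)
    records$rate_fitted <- as.numeric(stats::fitted(fit))
    records$rate_residual <- as.numeric(stats::residuals(fit))
    attr(records, "slope") <- unname(stats::coef(fit)[2])
    attr(records, "intercept") <- unname(stats::coef(fit)[1])
  }
  records
}

#' Fit the heating-rate phylogenetic mixed model
#'
#' Rock-residualized heating rate as the response, with total
#' reflectivity (percent), shell state (reference: dry), shell length
#' (mm) and the reflectivity x state interaction as fixed effects, and
#' species (Brownian covariance from the tree) and individual random
#' effects.
#'
#' @param records heating records ([read_heating_csv()] layout).
#' @param tree ultrametric `ape::phylo` covering the species.
#' @param seed integer seed for the sampler.
#' @param per_state passed to [rock_residualize()].
#' @param ... further arguments to [fit_pgmm()] (chains, iterations,
#'   burn_in, priors).
#' @return A list with `posterior` ([fit_pgmm()] result), `summary`
#'   ([summarize_posterior()] table) and `residual_table`.
#' @export
fit_heating_model <- function(records, tree, seed, per_state = FALSE, ...) {
  rt <- rock_residualize(records, per_state = per_state)
  design <- build_design(rt, response = "rate_residual",
                         fixed = ~ r_total + shell_length_mm + state +
                           r_total:state,
                         tree = tree, ref = list(state = "dry"))
  post <- fit_pgmm(design, seed = seed, ...)
  list(posterior = post, summary = summarize_posterior(post),
       residual_table = rt)
}

#' Predicted temperature difference from the reflectivity slope
#'
#' Temperature difference accumulated over a sun-exposure interval
#' between two shells differing in reflectivity, given the heating-rate
#' slope per percentage point of reflectivity:
#' `|slope| * delta_R * minutes`.
#'
#' @param slope_per_percent heating-rate slope (deg C min-1 per percent
#'   reflectivity; sign ignored).
#' @param delta_r reflectivity difference (percentage points).
#' @param minutes exposure duration (min, >= 0).
#' @return Temperature difference in deg C.
#' @export
#' @examples
#' predicted_difference(-0.02, 40, 2)  # 1.6 deg C
predicted_difference <- function(slope_per_percent, delta_r, minutes) {
  if (any(minutes < 0)) st_stop("minutes_invalid", "minutes must be >= 0")
  abs(slope_per_percent) * delta_r * minutes
}

#' Read / write a heating-experiment CSV
#'
#' Columns: `specimen,species,state,shell_length_mm,t_start_c,t_end_c,`
#' `elapsed_s,rock_t_c,r_total` (reflectivity in percent).
#'
#' @param path CSV path.
#' @return data.frame of heating records.
#' @export
read_heating_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "species", "state", "shell_length_mm", "t_start_c",
            "t_end_c", "elapsed_s", "rock_t_c", "r_total")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    st_stop("heating_columns",
            paste("missing heating columns:", paste(miss, collapse = ", ")))
  if (any(tab$elapsed_s <= 0)) st_stop("elapsed_invalid", "elapsed_s must be > 0")
  temps <- c(tab$t_start_c, tab$t_end_c, tab$rock_t_c)
  if (any(temps < -10 | temps > 80))
    st_stop("heating_range", "temperatures outside [-10, 80] deg C")
  tab
}

#' @rdname read_heating_csv
#' @param records data.frame of heating records to write.
#' @export
write_heating_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
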