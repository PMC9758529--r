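#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial positive sequence: consecutive autocorrelation pairs
#' are accumulated while their sum stays positive. A zero-variance
#' (degenerate) chain returns ESS = 1 with a warning.
#'
#' @param draws numeric vector, a single (possibly concatenated) chain of
#'   at least 100 draws.
#' @return Effective sample size (numeric).
#' @export
ess <- function(draws) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 100L) st_stop("ess_short", "need at least 100 draws for ESS")
  if (stats::var(draws) == 0) {
    st_warn("ess_degenerate", "zero-variance chain; ESS set to 1")
    return(1)
  }
  lag_max <- min(n - 1L, 10000L)
  rho <- as.numeric(stats::acf(draws, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    g <- rho[k] + rho[k + 1L]
    if (g <= 0) break
    s <- s + g
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' factor is computed over the resulting half-chains (between- vs
#' within-chain variance).
#'
#' @param chain_list list of numeric vectors, one per chain, equal
#'   lengths.
#' @return Split R-hat (numeric, >= ~1; NA if within-variance is zero and
#'   chains agree exactly, Inf if they disagree).
#' @export
split_rhat <- function(chain_list) {
  lens <- vapply(chain_list, length, 1L)
  if (length(unique(lens)) != 1L)
    st_stop("rhat_lengths", "chains have different lengths")
  half <- floor(lens[1] / 2)
  splits <- unlist(lapply(chain_list, function(ch) {
    list(ch[seq_len(half)], ch[seq(half + 1L, 2L * half)])
  }), recursive = FALSE)
  m <- length(splits)
  n <- half
  means <- vapply(splits, mean, 1)
  vars <- vapply(splits, stats::var, 1)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize a posterior as a Table-style data frame
#'
#' Per parameter: posterior mean ("Estimate"), empirical 2.5% and 97.5%
#' quantiles ("95% Credibility Interval"), effective sample size on the
#' pooled kept draws, and split R-hat across chains. Warnings are issued
#' when any split R-hat exceeds 1.1 (convergence) or any ESS falls below
#' 2000 (autocorrelation).
#'
#' @param post a `pgmm_posterior` from [fit_pgmm()], or a list of
#'   draw matrices with identical column names.
#' @param pretty rename design-matrix columns to publication-style
#'   parameter labels, default TRUE.
#' @return data.frame with columns `parameter`, `estimate`, `ci_low`,
#'   `ci_high`, `ess`, `rhat`; attribute `convergence_warning` is TRUE if
#'   any R-hat exceeded 1.1.
#' @export
summarize_posterior <- function(post, pretty = TRUE) {
  draws <- if (inherits(post, "pgmm_posterior")) post$draws else post
  if (length(unique(vapply(draws, nrow, 1L))) != 1L)
    st_stop("rhat_lengths", "chains have different lengths")
  pars <- colnames(draws[[1]])
  pooled <- do.call(rbind, draws)
  res <- lapply(pars, function(pn) {
    x <- pooled[, pn]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    e <- suppressWarnings(ess(x))
    r <- if (length(draws) >= 2L) {
      split_rhat(lapply(draws, function(d) d[, pn]))
    } else NA_real_
    data.frame(parameter = pn, estimate = mean(x), ci_low = q[1],
               ci_high = q[2], ess = e, rhat = r)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (pretty) out$parameter <- pretty_param(out$parameter)
  bad_rhat <- is.finite(out$rhat) & out$rhat > 1.1
  if (any(bad_rhat, na.rm = TRUE))
    st_warn("convergence", paste("split R-hat > 1.1 for:",
                                 paste(out$parameter[bad_rhat], collapse = ", ")))
  low_ess <- out$ess < 2000
  if (any(low_ess))
    message("ESS below 2000 for: ",
            paste(out$parameter[low_ess], collapse = ", "))
  attr(out, "convergence_warning") <- any(bad_rhat, na.rm = TRUE)
  out
}

# map design-matrix column names to publication-style labels
pretty_param <- function(x) {
  map <- c("(Intercept)" = "Intercept",
           "habitatexposed" = "Habitat (Exposed)",
           "statedry" = "State (Dry)",
           "statewet" = "State (Wet)",
           "habitatexposed:statedry" = "Habitat (Exposed):State (Dry)",
           "r_uv" = "UV-Visible reflectivity",
           "r_total" = "Total reflectivity",
           "shell_length_mm" = "Shell length",
           "r_total:statewet" = "Total reflectivity:State (Wet)",
           "sd_species" = "SD (Species)",
           "sd_individual" = "SD (Individual)",
           "sigma" = "Sigma (Residual)")
  out <- map[x]
  out[is.na(out)] <- x[is.na(out)]
  unname(out)
}
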