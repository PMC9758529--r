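#' Fit one of the reflectivity phylogenetic mixed models
#'
#' Three models share the fixed-effect structure microhabitat x shell
#' state (treatment coding, references sheltered and wet), with species
#' (Brownian covariance from the tree) and individual random effects.
#' The response is the total, UV-visible or NIR band reflectivity. For
#' the NIR band, the correlation with UV-visible reflectivity is handled
#' either by entering UV-visible reflectivity as a covariate (primary
#' variant) or by regressing NIR on UV-visible first and modelling the
#' residuals (sensitivity variant).
#'
#' @param records reflectivity table ([build_reflectivity_table()]
#'   layout).
#' @param tree ultrametric `ape::phylo` covering the species.
#' @param band `"total"`, `"uvvis"` or `"nir"`.
#' @param nir_variant `"covariate"` (default) or `"residual"`.
#' @param seed sampler seed.
#' @param ... further arguments to [fit_pgmm()].
#' @return A list with `posterior` and `summary`.
#' @export
fit_reflectivity_model <- function(records, tree,
                                   band = c("total", "uvvis", "nir"),
                                   nir_variant = c("covariate", "residual"),
                                   seed, ...) {
  band <- match.arg(band)
  nir_variant <- match.arg(nir_variant)
  records <- as.data.frame(records)
  if (band == "nir" && nir_variant == "residual") {
    records$nir_resid <- uv_nir_residuals(records)$residuals
    response <- "nir_resid"
    fixed <- ~ habitat * state
  } else {
    response <- switch(band, total = "R_total", uvvis = "R_uv", nir = "R_nir")
    fixed <- if (band == "nir") ~ R_uv + habitat * state else ~ habitat * state
  }
  if (band == "nir" && nir_variant == "covariate") {
    names(records)[names(records) == "R_uv"] <- "r_uv"
    fixed <- ~ r_uv + habitat * state
  }
  design <- build_design(records, response = response, fixed = fixed,
                         tree = tree,
                         ref = list(habitat = "sheltered", state = "wet"))
  post <- fit_pgmm(design, seed = seed, ...)
  list(posterior = post, summary = summarize_posterior(post))
}
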