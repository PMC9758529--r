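#' Prior set for the phylogenetic mixed model
#'
#' Weakly informative priors: Normal(0, 10) on the intercept, Normal(0, 50)
#' on slopes, and half-Student-t(df 3, scale 20) on the three scale
#' parameters (species, individual, residual standard deviations).
#'
#' @param intercept_sd,slope_sd prior standard deviations for fixed
#'   effects.
#' @param sd_df,sd_scale degrees of freedom and scale of the half-t prior
#'   on standard deviations.
#' @return A list of class `pgmm_priors`.
#' @export
pgmm_priors <- function(intercept_sd = 10, slope_sd = 50,
                        sd_df = 3, sd_scale = 20) {
  structure(list(intercept_sd = intercept_sd, slope_sd = slope_sd,
                 sd_df = sd_df, sd_scale = sd_scale),
            class = "pgmm_priors")
}

#' Build the design bundle for a phylogenetic mixed model
#'
#' Assembles the fixed-effect matrix (treatment coding), the species and
#' individual grouping indices, and the Brownian correlation matrix `A`
#' aligned to the species present in the data (ordered as in the tree).
#' Habitat and shell-state columns given as character are converted to
#' factors; reference levels default to `sheltered` and `wet` and may be
#' overridden via `ref` (the heating model uses reference `dry`).
#'
#' @param data data.frame, one row per measurement.
#' @param response name of the response column.
#' @param fixed right-hand-side formula for the fixed effects, e.g.
#'   `~ habitat * state`.
#' @param tree ultrametric `ape::phylo` containing every species in
#'   `data`, or `NULL` for a non-phylogenetic fit (`A` = identity).
#' @param species_col,individual_col grouping column names.
#' @param ref named list of factor reference levels.
#' @return A list of class `pgmm_design` with elements `X`, `y`,
#'   `species`, `s_idx`, `individual`, `i_idx`, `A`, `data`.
#' @export
build_design <- function(data, response, fixed, tree,
                         species_col = "species",
                         individual_col = "specimen",
                         ref = list(habitat = "sheltered", state = "wet")) {
  data <- as.data.frame(data)
  domain <- list(habitat = c("sheltered", "exposed"),
                 state = c("wet", "dry"))
  for (v in names(ref)) {
    if (!v %in% names(data)) next
    if (!is.factor(data[[v]])) {
      allowed <- domain[[v]] %||% sort(unique(as.character(data[[v]])))
      lev <- unique(c(ref[[v]], allowed))
      bad <- setdiff(unique(as.character(data[[v]])), lev)
      if (length(bad)) st_stop("design_levels",
                               paste("unknown", v, "level:", bad[1]))
      data[[v]] <- factor(data[[v]], levels = lev)
    } else {
      data[[v]] <- stats::relevel(data[[v]], ref = ref[[v]])
    }
  }
  if (!response %in% names(data))
    st_stop("design_response", paste("no response column", response))
  X <- stats::model.matrix(fixed, data = data)
  if (nrow(X) >= ncol(X) && qr(X)$rank < ncol(X))
    st_stop("design_rank", "fixed-effect design matrix is rank deficient")
  y <- as.numeric(data[[response]])

  sp <- as.character(data[[species_col]])
  if (is.null(tree)) {
    species <- sort(unique(sp))
    A <- diag(length(species))
    dimnames(A) <- list(species, species)
  } else {
    tree <- validate_phylogeny(tree)
    absent <- setdiff(unique(sp), tree$tip.label)
    if (length(absent))
      st_stop("species_missing",
              paste("species absent from tree:", paste(absent, collapse = ", ")))
    species <- intersect(tree$tip.label, unique(sp))
    A <- phylo_correlation(tree, species = species)
  }
  ind <- as.character(data[[individual_col]])
  individual <- unique(ind)
  structure(list(X = X, y = y,
                 species = species, s_idx = match(sp, species),
                 individual = individual, i_idx = match(ind, individual),
                 A = A, data = data, response = response, fixed = fixed),
            class = "pgmm_design")
}

# log density (unnormalised) of a half-Student-t prior on a scale s > 0
log_half_t <- function(s, df, scale) {
  -(df + 1) / 2 * log1p((s / scale)^2 / df)
}

# univariate slice sampler (stepping out + shrinkage), Neal (2003)
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started outside support")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# draw from N(Q^{-1} b, Q^{-1}) given precision Q and linear term b
draw_mvn_precision <- function(Q, b) {
  R <- chol(Q)
  mu <- backsolve(R, forwardsolve(t(R), b))
  as.numeric(mu + backsolve(R, stats::rnorm(length(b))))
}

#' Fit a Bayesian phylogenetic Gaussian mixed model by MCMC
#'
#' Gaussian response with fixed effects, a species random effect with
#' covariance `sigma_species^2 * A` (Brownian correlation from the tree),
#' an individual random effect, and residual noise. Sampling is
#' Metropolis-within-Gibbs: exact multivariate-normal conditional updates
#' for the fixed effects and both random-effect vectors, and univariate
#' slice-sampling updates on the log scale for the three standard
#' deviations under their half-Student-t priors. Deterministic for a
#' fixed seed.
#'
#' @param design a [build_design()] bundle.
#' @param priors a [pgmm_priors()] object.
#' @param chains,iterations,burn_in chain configuration; defaults 2
#'   chains of 6000 iterations with the first 2000 discarded.
#' @param seed integer seed (required); chain c uses `seed + c - 1`.
#' @param fix_sd optional named list fixing any of `species`,
#'   `individual`, `residual` standard deviations (used by oracle
#'   cross-checks).
#' @param thin keep every `thin`-th post-burn-in draw, default 1.
#' @return An object of class `pgmm_posterior`: list with `draws` (one
#'   kept-draws matrix per chain, columns = parameters), `design`,
#'   `config`.
#' @export
fit_pgmm <- function(design, priors = pgmm_priors(), chains = 2,
                     iterations = 6000, burn_in = 2000, seed,
                     fix_sd = list(), thin = 1) {
  stopifnot(inherits(design, "pgmm_design"))
  if (missing(seed)) st_stop("seed_required", "an explicit seed is required")
  if (burn_in >= iterations)
    st_stop("chain_config", "burn_in must be smaller than iterations")

  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  q_s <- length(design$species); q_i <- length(design$individual)
  s_idx <- design$s_idx; i_idx <- design$i_idx

  ev <- if (q_s > 0) {
    eigen(design$A, symmetric = TRUE)
  } else {
    list(values = numeric(0), vectors = matrix(0, 0, 0))
  }
  if (q_s > 0 && min(ev$values) < -1e-10)
    st_stop("corr_not_psd", "A is not positive semi-definite")
  vals <- pmax(ev$values, 1e-10)
  A_inv <- ev$vectors %*% (t(ev$vectors) / vals)

  prior_prec <- rep(1 / priors$slope_sd^2, p)
  icol <- which(colnames(X) == "(Intercept)")
  if (length(icol)) prior_prec[icol] <- 1 / priors$intercept_sd^2

  # combined location design C = [X | Zs | Zi]; all location parameters
  # (fixed effects and both random-effect vectors) are drawn jointly from
  # their exact Gaussian conditional, which removes the strong
  # intercept/random-effect posterior correlations from the Gibbs path
  Zs <- matrix(0, n, q_s); Zs[cbind(seq_len(n), s_idx)] <- 1
  Zi <- matrix(0, n, q_i); Zi[cbind(seq_len(n), i_idx)] <- 1
  C <- cbind(X, Zs, Zi)
  CtC <- crossprod(C)
  Cty <- as.numeric(crossprod(C, y))
  i_b <- seq_len(p); i_u <- p + seq_len(q_s); i_v <- p + q_s + seq_len(q_i)
  m <- p + q_s + q_i

  par_names <- c(colnames(X), "sd_species", "sd_individual", "sigma")
  kept_iters <- seq(burn_in + 1L, iterations, by = thin)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    beta <- numeric(p); u <- numeric(q_s); v <- numeric(q_i)
    s_init <- if (n > 1) max(stats::sd(y), 0.1) else 1
    if (!is.finite(s_init)) s_init <- 1
    sig_s <- fix_sd$species %||% s_init
    sig_i <- fix_sd$individual %||% s_init
    sig_e <- fix_sd$residual %||% s_init

    out <- matrix(NA_real_, length(kept_iters), p + 3L,
                  dimnames = list(NULL, par_names))
    krow <- 0L
    for (it in seq_len(iterations)) {
      if (n > 0) {
        Q <- CtC / sig_e^2
        Q[i_b, i_b] <- Q[i_b, i_b] + diag(prior_prec, p)
        Q[i_u, i_u] <- Q[i_u, i_u] + A_inv / sig_s^2
        diag(Q)[i_v] <- diag(Q)[i_v] + 1 / sig_i^2
        theta <- draw_mvn_precision(Q, Cty / sig_e^2)
        beta <- theta[i_b]; u <- theta[i_u]; v <- theta[i_v]
        resid <- y - as.numeric(C %*% theta)
      } else {
        beta <- stats::rnorm(p, 0, 1 / sqrt(prior_prec))
        u <- as.numeric(ev$vectors %*% (sqrt(vals) * stats::rnorm(q_s))) * sig_s
        v <- stats::rnorm(q_i, 0, sig_i)
        resid <- numeric(0)
      }
      # scale parameters: slice sampling on the log scale
      if (is.null(fix_sd$species)) {
        qu <- as.numeric(t(u) %*% A_inv %*% u)
        lp <- function(ls) {
          s <- exp(ls)
          -q_s * ls - qu / (2 * s^2) + log_half_t(s, priors$sd_df,
                                                  priors$sd_scale) + ls
        }
        sig_s <- exp(slice_sample1(log(sig_s), lp, w = 0.7))
      }
      if (is.null(fix_sd$individual)) {
        qv <- sum(v^2)
        lp <- function(ls) {
          s <- exp(ls)
          -q_i * ls - qv / (2 * s^2) + log_half_t(s, priors$sd_df,
                                                  priors$sd_scale) + ls
        }
        sig_i <- exp(slice_sample1(log(sig_i), lp, w = 0.7))
      }
      if (is.null(fix_sd$residual)) {
        ssr <- sum(resid^2)
        lp <- function(ls) {
          s <- exp(ls)
          -n * ls - ssr / (2 * s^2) + log_half_t(s, priors$sd_df,
                                                 priors$sd_scale) + ls
        }
        sig_e <- exp(slice_sample1(log(sig_e), lp, w = 0.7))
      }
      if (!all(is.finite(c(beta, sig_s, sig_i, sig_e))))
        st_stop("sampler_divergent",
                sprintf("non-finite state at iteration %d", it))
      if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
        krow <- krow + 1L
        out[krow, ] <- c(beta, sig_s, sig_i, sig_e)
      }
    }
    out
  }

  draws <- lapply(seq_len(chains), function(c) run_chain(seed + c - 1L))
  structure(list(draws = draws, design = design,
                 config = list(chains = chains, iterations = iterations,
                               burn_in = burn_in, seed = seed, thin = thin,
                               priors = priors)),
            class = "pgmm_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pgmm_posterior <- function(x, ...) {
  cat(sprintf("<pgmm_posterior> %d chains x %d kept draws, %d parameters\n",
              length(x$draws), nrow(x$draws[[1]]), ncol(x$draws[[1]])))
  invisible(x)
}

#' Generalized least squares oracle for the fixed effects
#'
#' Closed-form fixed-effect estimate with known variance components:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y` with
#' `V = sigma_species^2 Zs A Zs' + sigma_individual^2 Zi Zi' + sigma^2 I`.
#' With both random-effect variances zero this reduces to ordinary least
#' squares. Used as an independent cross-check of the MCMC sampler.
#'
#' @param design a [build_design()] bundle.
#' @param sigma_species,sigma_individual,sigma_resid known standard
#'   deviations.
#' @return Named vector of fixed-effect estimates.
#' @export
gls_oracle <- function(design, sigma_species, sigma_individual, sigma_resid) {
  X <- design$X; y <- design$y; n <- length(y)
  if (sigma_species == 0 && sigma_individual == 0) {
    fit <- stats::lm.fit(X, y)
    return(stats::setNames(as.numeric(fit$coefficients), colnames(X)))
  }
  Zs <- outer(design$s_idx, seq_along(design$species), `==`) * 1
  Zi <- outer(design$i_idx, seq_along(design$individual), `==`) * 1
  V <- sigma_species^2 * Zs %*% design$A %*% t(Zs) +
    sigma_individual^2 * tcrossprod(Zi) + sigma_resid^2 * diag(n)
  Vi <- tryCatch(solve(V), error = function(e)
    st_stop("gls_singular", "V is singular"))
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  stats::setNames(as.numeric(beta), colnames(X))
}
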