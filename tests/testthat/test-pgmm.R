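make_small_design <- function(seed = 1, n_sp = 5, n_ind = 2) {
  set.seed(seed)
  tree <- simulate_yule(n_sp, 1, seed = seed,
                        tip_labels = sprintf("species_%02d", 1:n_sp))
  df <- expand.grid(ind = seq_len(n_ind),
                    species = sprintf("species_%02d", 1:n_sp),
                    state = c("wet", "dry"), stringsAsFactors = FALSE)
  df$specimen <- paste0(df$species, "_", df$ind)
  df$habitat <- ifelse(match(df$species, unique(df$species)) %% 2 == 0,
                       "exposed", "sheltered")
  df$y <- rnorm(nrow(df), 10, 3)
  build_design(df, "y", ~ habitat * state, tree)
}

test_that("design uses treatment coding with sheltered/wet references", {
  tree <- fixture_tree(2)
  df <- data.frame(specimen = c("a", "b"),
                   species = c("species_01", "species_02"),
                   habitat = c("sheltered", "exposed"),
                   state = c("wet", "dry"), y = c(1, 2))
  d <- build_design(df, "y", ~ habitat * state, tree)
  expect_equal(unname(d$X[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(d$X[2, ]), c(1, 1, 1, 1))
  expect_identical(colnames(d$X)[1], "(Intercept)")

  # heating-style reference: dry
  d2 <- build_design(df, "y", ~ state, tree, ref = list(state = "dry"))
  expect_identical(colnames(d2$X)[2], "statewet")

  expect_error(build_design(transform(df, habitat = c("reef", "exposed")),
                            "y", ~ habitat * state, tree),
               class = "design_levels")
  expect_error(build_design(transform(df, species = c("nope", "species_02")),
                            "y", ~ habitat * state, tree),
               class = "species_missing")
  df4 <- rbind(df, df)
  df4$z <- 1  # constant column collides with the intercept
  expect_error(build_design(df4, "y", ~ habitat + z, tree),
               class = "design_rank")
})

test_that("NIR covariate model adds a UV-visible design column and synthetic bookkeeping holds", {
  g <- gen_reflectivity_study(seed = 3)
  expect_equal(nrow(g$records), 114)
  rec <- g$records
  names(rec)[names(rec) == "R_uv"] <- "r_uv"
  d <- build_design(rec, "R_nir", ~ r_uv + habitat * state, g$tree)
  expect_true("r_uv" %in% colnames(d$X))
  expect_equal(length(d$species), 19)
  expect_equal(length(d$individual), 57)
  expect_equal(dim(d$X), c(114, 5))
})

test_that("GLS oracle reduces to OLS and matches a dense random-intercept computation", {
  d <- make_small_design(2)
  ols <- unname(stats::lm.fit(d$X, d$y)$coefficients)
  expect_equal(unname(gls_oracle(d, 0, 0, 1)), ols, tolerance = 1e-10)

  # A = identity: compare against an independent dense-matrix computation
  d_id <- d
  d_id$A <- diag(length(d$species))
  n <- length(d$y)
  Zs <- outer(d$s_idx, seq_along(d$species), `==`) * 1
  Zi <- outer(d$i_idx, seq_along(d$individual), `==`) * 1
  V <- 4 * Zs %*% t(Zs) + 1 * Zi %*% t(Zi) + 2.25 * diag(n)
  Vi <- solve(V)
  beta_dense <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% d$y)
  expect_equal(unname(gls_oracle(d_id, 2, 1, 1.5)),
               as.numeric(beta_dense), tolerance = 1e-8)
})

test_that("sampler posterior means match the GLS oracle with fixed variance components", {
  for (seed in 1:5) {
    d <- make_small_design(seed)
    sds <- list(species = 2, individual = 1, residual = 1.5)
    post <- fit_pgmm(d, priors = pgmm_priors(intercept_sd = 1e4,
                                             slope_sd = 1e4),
                     chains = 2, iterations = 3000, burn_in = 500,
                     seed = seed, fix_sd = sds)
    pooled <- do.call(rbind, post$draws)
    oracle <- gls_oracle(d, sds$species, sds$individual, sds$residual)
    for (pn in colnames(d$X)) {
      draws <- pooled[, pn]
      mcse <- sd(draws) / sqrt(suppressWarnings(ess(draws)))
      expect_lt(abs(mean(draws) - oracle[[pn]]), 3 * mcse + 1e-8)
    }
  }
})

test_that("sampler collapses on the truth for noiseless data", {
  tree <- fixture_tree(4)
  df <- expand.grid(ind = 1:2, species = sprintf("species_%02d", 1:4),
                    state = c("wet", "dry"), stringsAsFactors = FALSE)
  df$specimen <- paste0(df$species, "_", df$ind)
  df$habitat <- ifelse(df$species %in% c("species_01", "species_02"),
                       "exposed", "sheltered")
  beta <- c(10, 5, 2, 3)
  X <- cbind(1, (df$habitat == "exposed") * 1, (df$state == "dry") * 1,
             (df$habitat == "exposed") * (df$state == "dry") * 1)
  df$y <- as.numeric(X %*% beta)
  d <- build_design(df, "y", ~ habitat * state, tree)
  post <- fit_pgmm(d, chains = 1, iterations = 1500, burn_in = 500, seed = 4,
                   fix_sd = list(species = 1e-6, individual = 1e-6,
                                 residual = 1e-6))
  est <- colMeans(post$draws[[1]])
  expect_equal(unname(est[1:4]), beta, tolerance = 1e-3)
})

test_that("with no data the sampler reproduces the priors", {
  df <- data.frame(specimen = character(0), species = character(0),
                   x1 = numeric(0), y = numeric(0))
  d <- build_design(df, "y", ~ x1, tree = NULL)
  post <- fit_pgmm(d, chains = 2, iterations = 6000, burn_in = 1000,
                   seed = 12)
  pooled <- do.call(rbind, post$draws)
  # intercept ~ Normal(0, 10); slope ~ Normal(0, 50)
  expect_lt(abs(mean(pooled[, "(Intercept)"])), 0.5)
  expect_lt(abs(sd(pooled[, "(Intercept)"]) - 10), 0.5)
  expect_lt(abs(sd(pooled[, "x1"]) - 50), 2.5)
  expect_lt(abs(quantile(pooled[, "x1"], 0.975)[[1]] - 1.96 * 50), 8)
  # scale parameters follow the half-t(3, 0, 20) prior: median ~ 15.31
  half_t_median <- 20 * qt(0.75, df = 3)
  expect_lt(abs(median(pooled[, "sigma"]) - half_t_median),
            0.1 * half_t_median)
})

test_that("sampler is deterministic under a fixed seed and requires one", {
  d <- make_small_design(6)
  p1 <- fit_pgmm(d, chains = 1, iterations = 300, burn_in = 100, seed = 9)
  p2 <- fit_pgmm(d, chains = 1, iterations = 300, burn_in = 100, seed = 9)
  expect_identical(p1$draws, p2$draws)
  expect_error(fit_pgmm(d, chains = 1, iterations = 300, burn_in = 100),
               class = "seed_required")
  expect_error(fit_pgmm(d, iterations = 100, burn_in = 100, seed = 1),
               class = "chain_config")
})
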