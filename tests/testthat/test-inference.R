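test_that("mcmc_config enforces its invariants and the 4000-draw default", {
  cfg <- mcmc_config()
  expect_equal(n_retained_draws(cfg), 4000)
  expect_error(mcmc_config(n_iterations = 500, n_warmup = 500), "n_warmup")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("sample_posterior retains the configured draws reproducibly", {
  sim <- simulate_dataset(simulation_design(5, 3, seed = 21))
  cfg <- mcmc_config(n_iterations = 900, n_warmup = 300, seed = 22)
  fit1 <- suppressWarnings(sample_posterior(sim$data, cfg = cfg))
  fit2 <- suppressWarnings(sample_posterior(sim$data, cfg = cfg))
  expect_identical(fit1$draws, fit2$draws)
  expect_equal(dim(fit1$draws), c(300, 2, 2 + 2 * 5))
  expect_true(all(c("mu", "sigma", "mu_i[P01]", "sigma_i[P01]") %in%
    dimnames(fit1$draws)[[3]]))
  expect_true(all(extract_draws(fit1, "sigma") > 0))
  expect_true(all(extract_draws(fit1, "sigma_i[P03]") > 0))
  expect_equal(nrow(fit1$diagnostics), dim(fit1$draws)[3])
  expect_true(all(is.finite(fit1$diagnostics$rhat)))

  # a default-config fit retains exactly 4000 draws
  fit3 <- suppressWarnings(sample_posterior(sim$data, cfg = mcmc_config(seed = 23)))
  expect_equal(prod(dim(fit3$draws)[1:2]), 4000)
})

test_that("single-observation products are allowed with a warning", {
  d <- vm_dataset(data.frame(
    product = c("A", "A", "B"), batch = c("b1", "b2", "b1"),
    cycle = NA, value = c(0.1, -0.2, 0.3)
  ))
  w <- capture_warnings(
    sample_posterior(d, cfg = mcmc_config(n_iterations = 400, n_warmup = 150, seed = 1))
  )
  expect_true(any(grepl("single observation", w)))
})

test_that("posterior mean of mu matches the grid-quadrature oracle", {
  y <- c(-0.3, 0.5)
  d <- vm_dataset(data.frame(
    product = "A", batch = c("b1", "b2"), cycle = NA, value = y
  ))
  fit <- suppressWarnings(sample_posterior(d, cfg = mcmc_config(seed = 5)))
  mu <- as.vector(extract_draws(fit, "mu"))
  ess <- fit$diagnostics$ess[fit$diagnostics$parameter == "mu"]
  mcse <- sd(mu) / sqrt(ess)
  oracle <- grid_posterior_mean_mu(y, n_grid = 45)
  expect_lt(abs(mean(mu) - oracle), 3 * mcse)
})

test_that("posterior recovers the truth on a large simulated dataset", {
  sim <- simulate_dataset(simulation_design(50, 50, seed = 31))
  fit <- suppressWarnings(sample_posterior(sim$data, cfg = mcmc_config(seed = 32)))
  mu <- as.vector(extract_draws(fit, "mu"))
  sigma <- as.vector(extract_draws(fit, "sigma"))
  expect_lt(abs(mean(mu) - 0.1), 3 * sd(mu))
  expect_lt(abs(mean(sigma) - 0.4), 3 * sd(sigma))
  ci_mu <- quantile(mu, c(0.005, 0.995))
  ci_sg <- quantile(sigma, c(0.005, 0.995))
  expect_true(ci_mu[1] <= mean(mu) && mean(mu) <= ci_mu[2])
  expect_true(ci_sg[1] <= mean(sigma) && mean(sigma) <= ci_sg[2])
  diag_core <- fit$diagnostics[fit$diagnostics$parameter %in% c("mu", "sigma"), ]
  expect_true(all(diag_core$rhat <= 1.05))
  expect_true(all(diag_core$ess > 400))
})

test_that("rhat reproduces the direct split formula and detects non-mixing", {
  chains <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(rhat(do.call(cbind, chains)), split_rhat_direct(chains),
               tolerance = 1e-12)

  set.seed(41)
  x <- matrix(rnorm(2e4), ncol = 2)
  r <- rhat(x)
  # converged iid chains: 1 up to finite-sample noise in the variance ratio
  expect_lt(abs(r - 1), 0.01)

  disjoint <- cbind(rnorm(100, 0, 1e-3), rnorm(100, 100, 1e-3))
  expect_gt(rhat(disjoint), 1.5)

  expect_error(rhat(matrix(1:8, ncol = 1)), "2 chains")
  expect_error(rhat(matrix(1:4, ncol = 2)), "4 draws")
  expect_warning(r0 <- rhat(matrix(1, 10, 2)), "zero within-chain variance")
  expect_true(is.nan(r0))
})

test_that("effective_sample_size matches iid and AR(1) oracles", {
  set.seed(42)
  x <- matrix(rnorm(4000), ncol = 2)
  expect_lt(abs(effective_sample_size(x) / 4000 - 1), 0.15)

  # AR(1) with rho = 0.5: ESS ~ n (1 - rho) / (1 + rho) = n / 3
  n <- 1e4
  rho <- 0.5
  ar <- numeric(n)
  innov <- rnorm(n, 0, sqrt(1 - rho^2))
  ar[1] <- rnorm(1)
  for (t in 2:n) ar[t] <- rho * ar[t - 1] + innov[t]
  ess_ar <- effective_sample_size(matrix(ar, ncol = 1))
  expect_lt(abs(ess_ar / (n / 3) - 1), 0.2)

  # duplicating every draw at most halves the relative ESS
  base <- rnorm(2000)
  dup <- rep(base, each = 2)
  ess_dup <- effective_sample_size(matrix(dup, ncol = 1))
  expect_lt(ess_dup, 0.55 * length(dup))

  expect_warning(e0 <- effective_sample_size(matrix(1, 10, 2)), "constant")
  expect_true(is.nan(e0))
})

test_that("posterior_predictive_S matches closed-form lognormal quantiles", {
  # degenerate posterior fixed at the reference population (0.1, 0.4)
  fit <- make_fixed_fit(0.1, 0.4, n = 1e6)
  set.seed(51)
  S <- posterior_predictive_S(fit)
  expect_true(all(S > 0))
  expect_equal(length(S), 1e6)
  expect_lt(abs(median(S) - exp(0.1)), 0.01)
  pi95 <- equal_tailed_interval(S, 0.95)
  expect_lt(abs(pi95[1] - exp(0.1 - 1.96 * 0.4)), 0.01)
  expect_lt(abs(pi95[2] - exp(0.1 + 1.96 * 0.4)), 0.03)

  # point-mass population: S = e^mu exactly
  fit0 <- make_fixed_fit(0.1, 0, n = 100)
  expect_equal(as.numeric(posterior_predictive_S(fit0)), rep(exp(0.1), 100),
               tolerance = 1e-15)
})

test_that("credible_interval uses the equal-tailed quantile rule", {
  a <- array(1:100, dim = c(50, 2, 1), dimnames = list(NULL, NULL, "mu"))
  fit <- structure(list(draws = a), class = "vm_fit")
  # type-7 percentiles of 1..100 at 2.5% / 97.5%, computed by hand:
  # 1 + 0.025 * 99 and 1 + 0.975 * 99
  expect_equal(credible_interval(fit, "mu", 0.95), c(3.475, 97.525),
               tolerance = 1e-12)
  wide <- credible_interval(fit, "mu", 0.99999)
  expect_lt(abs(wide[1] - 1), 0.01)
  expect_lt(abs(wide[2] - 100), 0.01)
  const <- structure(
    list(draws = array(7, dim = c(10, 2, 1), dimnames = list(NULL, NULL, "mu"))),
    class = "vm_fit"
  )
  expect_equal(credible_interval(const, "mu", 0.95), c(7, 7))
  expect_error(credible_interval(fit, "nope", 0.95), "unknown parameter")
  expect_error(credible_interval(fit, "mu", 1.2), "level")
})
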