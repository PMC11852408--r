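test_that("log_prior matches hand-derived normal/half-normal values", {
  pop <- population_params(0, 1)
  pr <- prior_config()

  # N(0|0,1) at mode plus half-normal at 1: hand-summed log pdf formulas
  expected <- -0.5 * log(2 * pi) - (0.5 * log(2 * pi) + 0.5 - log(2))
  expect_equal(log_prior(pop, list(), pr), expected, tolerance = 1e-12)

  # doubling mu_prior_sd with mu = 0 changes only the mu-term, by -ln 2
  expect_equal(
    log_prior(pop, list(), prior_config(mu_prior_sd = 2)) -
      log_prior(pop, list(), pr),
    -log(2),
    tolerance = 1e-12
  )

  # wider priors yield strictly decreasing density at a near-mode point
  vals <- vapply(1:5, function(s) {
    log_prior(
      population_params(0, 0.1), list(),
      prior_config(mu_prior_sd = s, sigma_prior_sd = s)
    )
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  # product terms: normal on mu_i, uniform (zero) on p_i
  eff <- product_effects(mu_i = 0.3, sigma_i = 0.5, p_i = 0.25)
  expect_equal(
    log_prior(pop, list(eff), pr),
    expected + dnorm(0.3, 0, 5, log = TRUE),
    tolerance = 1e-12
  )

  expect_error(log_prior(population_params(0, 0), list(), pr), "sigma")
})

test_that("loglik_single_cycle matches hand-computed normal log pdfs", {
  eff <- product_effects(mu_i = 0, sigma_i = 1)
  expect_equal(loglik_single_cycle(0, eff), -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(loglik_single_cycle(c(0, 1), eff), -log(2 * pi) - 0.5,
               tolerance = 1e-12)
  expect_error(loglik_single_cycle(numeric(0), eff), "empty")

  # location invariance under joint translation
  set.seed(1)
  for (rep in 1:10) {
    y <- rnorm(5)
    mu_i <- rnorm(1)
    s <- runif(1, 0.2, 2)
    shift <- rnorm(1, sd = 10)
    expect_equal(
      loglik_single_cycle(y, product_effects(mu_i, s)),
      loglik_single_cycle(y + shift, product_effects(mu_i + shift, s)),
      tolerance = 1e-9
    )
  }
})

test_that("loglik_multi_cycle matches hand-derived values and MVN marginal", {
  eff <- product_effects(mu_i = 0, sigma_i = sqrt(2), tau_i = 1, nu_i = 1)
  expect_equal(
    loglik_multi_cycle(list(0), eff, batch_effects(0)),
    -log(2 * pi),
    tolerance = 1e-12
  )

  # density at the mode decreases as tau grows (1/tau normalization)
  eff2 <- product_effects(mu_i = 0, sigma_i = sqrt(8), tau_i = 2, nu_i = 2)
  expect_lt(
    loglik_multi_cycle(list(0), eff2, batch_effects(0)),
    loglik_multi_cycle(list(0), eff, batch_effects(0))
  )

  expect_error(
    loglik_multi_cycle(list(0), product_effects(0, 1, p_i = 0), batch_effects(0)),
    "tau_i"
  )
  expect_error(
    loglik_multi_cycle(list(0), product_effects(0, 1), batch_effects(0)),
    "split"
  )

  # Monte-Carlo marginal over batch means agrees with the closed-form MVN
  y <- c(0.1, -0.2)
  mu_i <- 0.05
  tau <- 0.3
  nu <- 0.2
  eff3 <- product_effects(mu_i, sqrt(tau^2 + nu^2), tau_i = tau, nu_i = nu)
  set.seed(7)
  n_mc <- 2e5
  mu_ij <- rnorm(n_mc, mu_i, tau)
  dens <- exp(
    dnorm(y[1], mu_ij, nu, log = TRUE) + dnorm(y[2], mu_ij, nu, log = TRUE)
  )
  mc_se <- sd(dens) / sqrt(n_mc)
  expect_lt(
    abs(mean(dens) - exp(mvn_batch_marginal_logpdf(y, mu_i, tau, nu))),
    3 * mc_se
  )

  # the hierarchical form at a given batch mean is consistent with the
  # factorization dens(mu_ij) * lik(y | mu_ij)
  expect_equal(
    loglik_multi_cycle(list(y), eff3, batch_effects(0.1)),
    dnorm(0.1, mu_i, tau, log = TRUE) + sum(dnorm(y, 0.1, nu, log = TRUE)),
    tolerance = 1e-12
  )
})

test_that("log_random_effect is the lognormal density with Jacobian", {
  pop <- population_params(0.1, 0.4)
  # at the population median sigma_i = e^mu: hand-evaluated lognormal pdf
  expect_equal(
    log_random_effect(product_effects(0, exp(0.1)), pop),
    -0.5 * log(2 * pi) - log(0.4) - 0.1,
    tolerance = 1e-12
  )
  expect_equal(
    log_random_effect(product_effects(0, 1), population_params(0, 1)),
    -0.5 * log(2 * pi),
    tolerance = 1e-12
  )
  expect_error(log_random_effect(product_effects(0, 1), population_params(0, 0)),
               "sigma")

  # normalization over sigma_i by adaptive quadrature
  dens <- function(s) {
    vapply(s, function(si) {
      exp(log_random_effect(product_effects(0, si), pop))
    }, numeric(1))
  }
  total <- integrate(dens, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("product_effects enforces the variance decomposition", {
  set.seed(2)
  for (rep in 1:25) {
    sigma_i <- runif(1, 0.1, 3)
    p <- runif(1)
    eff <- product_effects(0, sigma_i, p_i = p)
    expect_lt(abs(eff$tau_i^2 + eff$nu_i^2 - sigma_i^2), 1e-10 * sigma_i^2)
    expect_equal(eff$p_i, p, tolerance = 1e-12)
  }
  expect_error(product_effects(0, 1, tau_i = 0.9, nu_i = 0.9), "violated")
  expect_error(product_effects(0, -1), "sigma_i")
  expect_error(product_effects(0, 1, p_i = 1.5), "p_i")
})

test_that("log_posterior_unnormalized decomposes additively and checks modes", {
  data <- toy_mixed_dataset()
  pop <- population_params(0.05, 0.5)
  pr <- prior_config()
  eff <- list(
    S1 = product_effects(0.1, 0.3),
    M1 = product_effects(0.05, 0.25, p_i = 0.4)
  )
  bm <- list(M1 = batch_effects(c(0.0, 0.15)))
  lp <- log_posterior_unnormalized(data, pop, eff, bm, pr)
  manual <- log_prior(pop, eff, pr) +
    log_random_effect(eff$S1, pop) + log_random_effect(eff$M1, pop) +
    loglik_single_cycle(product_data(data, "S1"), eff$S1) +
    loglik_multi_cycle(product_data(data, "M1"), eff$M1, bm$M1)
  expect_equal(lp, manual, tolerance = 1e-12)

  # one product, y = {0}, reference parameters: hand-summed component pdfs
  d1 <- vm_dataset(data.frame(product = "A", batch = "b1", cycle = NA, value = 0))
  lp1 <- log_posterior_unnormalized(
    d1, population_params(0, 1), list(A = product_effects(0, 1)), list(), pr
  )
  expected <- (-0.5 * log(2 * pi) - (0.5 * log(2 * pi) + 0.5 - log(2)) +
    dnorm(0, 0, 5, log = TRUE)) + (-0.5 * log(2 * pi)) + (-0.5 * log(2 * pi))
  expect_equal(lp1, expected, tolerance = 1e-12)

  # location invariance: shift one product's data and mean together
  data_shift <- as.data.frame(data)
  data_shift$value[data_shift$product == "S1"] <-
    data_shift$value[data_shift$product == "S1"] + 3
  eff_shift <- eff
  eff_shift$S1 <- product_effects(0.1 + 3, 0.3)
  lp_shift <- log_posterior_unnormalized(vm_dataset(data_shift), pop, eff_shift, bm, pr)
  delta_prior <- dnorm(3.1, 0, 5, log = TRUE) - dnorm(0.1, 0, 5, log = TRUE)
  expect_equal(lp_shift - lp, delta_prior, tolerance = 1e-9)

  # structural errors
  expect_error(
    log_posterior_unnormalized(
      data, pop,
      list(S1 = product_effects(0.1, 0.3, p_i = 0.5), M1 = eff$M1), bm, pr
    ),
    "multi-cycle parameters"
  )
  expect_error(
    log_posterior_unnormalized(data, pop, eff, list(), pr),
    "missing batch means"
  )
  expect_error(
    log_posterior_unnormalized(
      data, pop, eff, c(bm, list(S1 = batch_effects(0))), pr
    ),
    "non-multi-cycle"
  )
})

test_that("compiled joint density equals the R assembly plus Jacobians", {
  data <- toy_mixed_dataset()
  md <- varmeta:::.vm_model_data(data)
  pr <- prior_config()
  set.seed(11)
  for (rep in 1:10) {
    # unconstrained draw: mu, eta, mu_i x2, u_i x2, q, z x2
    th <- rnorm(9, 0, 0.8)
    cpp <- varmeta:::vm_lp_grad(th, md, unclass(pr))
    ids <- md$ids # model order
    sigma <- exp(th[2])
    lam <- th[1] + sigma * th[5:6] # ln sigma_i via the non-centered map
    p <- plogis(th[7])
    eff <- list()
    eff[[ids[1]]] <- if (md$modes[1] == 1) {
      product_effects(th[3], exp(lam[1]), p_i = p)
    } else {
      product_effects(th[3], exp(lam[1]))
    }
    eff[[ids[2]]] <- if (md$modes[2] == 1) {
      product_effects(th[4], exp(lam[2]), p_i = p)
    } else {
      product_effects(th[4], exp(lam[2]))
    }
    multi_id <- ids[md$modes == 1]
    tau <- eff[[multi_id]]$tau_i
    z <- th[8:9] # the two batch z's occupy the tail of the layout
    mu_ij <- eff[[multi_id]]$mu_i + tau * z
    r_lp <- log_posterior_unnormalized(
      data, population_params(th[1], sigma), eff,
      stats::setNames(list(batch_effects(mu_ij)), multi_id), pr
    )
    n_batches_multi <- length(mu_ij)
    # change-of-variables terms: log-scale sigma, non-centered log-SDs
    # (eta + lam_i each), logit p, non-centered batch means (log tau each)
    jacobian <- th[2] + sum(th[2] + lam) + log(p) + log(1 - p) +
      n_batches_multi * log(tau)
    expect_equal(cpp$lp, r_lp + jacobian, tolerance = 1e-8)
  }
})

test_that("compiled gradient matches central finite differences", {
  data <- toy_mixed_dataset()
  md <- varmeta:::.vm_model_data(data)
  pr <- prior_config()
  set.seed(12)
  th <- rnorm(9, 0, 0.6)
  # dimension: 2 + 2*2 products + 1 q + 2 z = 9
  res <- varmeta:::vm_lp_grad(th, md, unclass(pr))
  expect_equal(res$dim, 9)
  eps <- 1e-6
  fd <- vapply(seq_along(th), function(i) {
    tp <- th
    tp[i] <- tp[i] + eps
    tm <- th
    tm[i] <- tm[i] - eps
    (varmeta:::vm_lp_grad(tp, md, unclass(pr))$lp -
      varmeta:::vm_lp_grad(tm, md, unclass(pr))$lp) / (2 * eps)
  }, numeric(1))
  expect_equal(res$grad, fd, tolerance = 1e-5)
})
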