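# Independent oracles used across the suite. Each is a direct transcription
# of a textbook formula or a brute-force numerical scheme, deliberately kept
# separate from the package's own code paths.

# --- 4-D grid-quadrature posterior for a 1-product single-cycle toy --------
# Hand-written joint density (prior x population x likelihood) on the
# unconstrained scale (eta = ln sigma, lam = ln sigma_i), integrated on a
# tensor grid. Returns the posterior mean of mu.
grid_posterior_mean_mu <- function(y, n_grid = 45,
                                   mu_prior_sd = 1, sigma_prior_sd = 1,
                                   product_mean_prior_sd = 5) {
  ybar <- mean(y)
  mu_g <- seq(-3.5, 3.5, length.out = n_grid)
  eta_g <- seq(-3.5, 1.5, length.out = n_grid)
  mui_g <- seq(ybar - 5, ybar + 5, length.out = n_grid)
  lam_g <- seq(-4.5, 2.5, length.out = n_grid)
  num <- 0
  den <- 0
  for (mui in mui_g) {
    loglik_by_lam <- vapply(lam_g, function(lam) {
      sum(dnorm(y, mui, exp(lam), log = TRUE))
    }, numeric(1))
    for (k in seq_along(lam_g)) {
      lam <- lam_g[k]
      # matrix over (mu, eta): population term + priors
      lp <- outer(mu_g, eta_g, function(mu, eta) {
        dnorm(mu, 0, mu_prior_sd, log = TRUE) +
          log(2) + dnorm(exp(eta), 0, sigma_prior_sd, log = TRUE) + eta +
          dnorm(lam, mu, exp(eta), log = TRUE)
      })
      w <- exp(lp + loglik_by_lam[k] + dnorm(mui, 0, product_mean_prior_sd, log = TRUE))
      sw <- sum(w)
      num <- num + sum(rowSums(w) * mu_g)
      den <- den + sw
    }
  }
  num / den
}

# --- closed-form marginal MVN density of one multi-cycle batch -------------
# cycle values of a batch, with the batch mean integrated out analytically:
# y ~ MVN(mu_i * 1, nu^2 I + tau^2 J). Log density via Sherman-Morrison.
mvn_batch_marginal_logpdf <- function(y, mu_i, tau, nu) {
  n <- length(y)
  d <- y - mu_i
  logdet <- (n - 1) * log(nu^2) + log(nu^2 + n * tau^2)
  quad <- sum(d^2) / nu^2 -
    (tau^2 / (nu^2 * (nu^2 + n * tau^2))) * sum(d)^2
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

# --- direct transcription of the split R-hat formula -----------------------
split_rhat_direct <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    h <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[1:h]), list(ch[(h + 1):(2 * h)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# --- exact-posterior stub (normal model, Jeffreys prior) -------------------
# For iid y ~ N(mu, sigma^2) with prior p(mu, sigma^2) proportional to
# 1/sigma^2, the posterior equal-tailed intervals coincide with the exact
# frequentist t- and chi-square intervals, so CI coverage of the stub is
# exactly nominal. Used to validate the study harness independently of the
# MCMC sampler.
fit_nix_stub <- function(data, prior, mcmc) {
  y <- data$value
  n <- length(y)
  ybar <- mean(y)
  s2 <- var(y)
  ndraw <- 4000
  set.seed(mcmc$seed)
  sigma2 <- (n - 1) * s2 / rchisq(ndraw, df = n - 1)
  mu <- rnorm(ndraw, ybar, sqrt(sigma2 / n))
  a <- array(
    c(mu, sqrt(sigma2)), dim = c(ndraw / 2, 2, 2),
    dimnames = list(NULL, c("chain1", "chain2"), c("mu", "sigma"))
  )
  structure(
    list(
      draws = a,
      diagnostics = data.frame(
        parameter = c("mu", "sigma"), rhat = NA_real_, ess = NA_real_
      ),
      divergences = 0L
    ),
    class = "vm_fit"
  )
}

sim_normal_stub <- function(design) {
  set.seed(design$seed)
  y <- rnorm(design$n_batches, design$pop$mu, design$pop$sigma)
  list(
    data = vm_dataset(data.frame(
      product = "X", batch = paste0("b", seq_along(y)),
      cycle = NA_character_, value = y
    )),
    truth = list(pop = design$pop)
  )
}

# --- small helpers ---------------------------------------------------------
make_fixed_fit <- function(mu, sigma, n = 4000) {
  a <- array(
    c(rep(mu, n), rep(sigma, n)), dim = c(n / 2, 2, 2),
    dimnames = list(NULL, c("chain1", "chain2"), c("mu", "sigma"))
  )
  structure(list(draws = a), class = "vm_fit")
}

toy_mixed_dataset <- function() {
  df <- data.frame(
    product = c(rep("S1", 3), rep("M1", 6)),
    batch = c("b1", "b2", "b3", rep(c("b1", "b2"), each = 3)),
    cycle = c(NA, NA, NA, rep(c("c1", "c2", "c3"), 2)),
    value = c(0.2, -0.1, 0.4, 0.15, 0.05, -0.2, 0.3, 0.1, 0.0)
  )
  vm_dataset(df)
}
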