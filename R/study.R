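#' Simulation-study scenario
#'
#' One cell of the simulation study: a data-generating design, the prior and
#' sampler settings used for every fit, and the number of replicates.
#'
#' @param design A [simulation_design()]; its `seed` acts as the root seed
#'   of the scenario (per-replicate seeds are derived with [child_seed()]).
#' @param prior A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param n_sim Number of generate-fit-evaluate replicates (>= 2; the
#'   reference study uses 1000, desk-scale runs typically 100-200).
#' @param label Free-text scenario label.
#' @return An object of class `vm_scenario`.
#' @export
scenario <- function(design, prior = prior_config(), mcmc = mcmc_config(),
                     n_sim = 1000, label = "") {
  stopifnot(inherits(design, "vm_design"), n_sim >= 2)
  structure(
    list(
      design = design, prior = prior, mcmc = mcmc,
      n_sim = as.integer(n_sim), label = label
    ),
    class = "vm_scenario"
  )
}

#' Empirical standard error of replicate estimates
#'
#' Sample standard deviation (denominator `n - 1`) of per-replicate point
#' estimates.
#'
#' @param estimates Numeric vector, length >= 2.
#' @return The empirical SE.
#' @export
empirical_se <- function(estimates) {
  if (length(estimates) < 2) stop("need at least 2 estimates")
  stats::sd(estimates)
}

#' Non-parametric bootstrap percentile interval
#'
#' Resamples `values` with replacement (resample size = input size) `n_boot`
#' times, applies `stat` to each resample and returns the 2.5% and 97.5%
#' percentiles of the resampled statistics.
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param stat Aggregating function (default `mean`).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_interval <- function(values, n_boot = 10000, stat = mean,
                               seed = NULL) {
  n <- length(values)
  if (n == 0) stop("`values` must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  stats_boot <- vapply(seq_len(n_boot), function(b) {
    stat(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  unname(stats::quantile(stats_boot, c(0.025, 0.975)))
}

#' Coverage proportion with bootstrap uncertainty
#'
#' @param indicators Vector of 0/1 (or logical) coverage indicators.
#' @param n_boot Bootstrap resamples for the companion interval.
#' @param seed Optional integer seed.
#' @return List with `estimate` (mean of the indicators) and `interval`
#'   (bootstrap percentile 95% interval of the mean).
#' @export
coverage <- function(indicators, n_boot = 10000, seed = NULL) {
  x <- as.numeric(indicators)
  if (length(x) == 0) stop("`indicators` must be non-empty")
  if (!all(x %in% c(0, 1))) stop("`indicators` must be 0/1")
  list(
    estimate = mean(x),
    interval = bootstrap_interval(x, n_boot = n_boot, seed = seed)
  )
}

#' Run one simulation-study scenario
#'
#' For each replicate: derive child seeds from the scenario root seed,
#' generate a fresh dataset, fit the model, and record the posterior means
#' of \eqn{\mu} and \eqn{\sigma}, their equal-tailed 95% credible intervals,
#' the 95% predictive interval of a future product's SD, and whether a
#' freshly drawn future-product SD \eqn{\sigma_{new} \sim
#' \mathrm{LogNormal}(\mu_{true}, \sigma_{true})} falls inside it.
#' Replicates whose fit fails or whose split R-hat exceeds
#' `rhat_threshold` for any parameter are recorded but excluded from the
#' aggregates (the exclusion count is reported); a replicate failure never
#' aborts the scenario.
#'
#' @param sc A [scenario()].
#' @param level Interval mass for CIs and PIs (default 0.95).
#' @param rhat_threshold Convergence cut-off (default 1.05).
#' @param n_boot Bootstrap resamples for aggregate intervals (default
#'   10000).
#' @param fit_fn Fitting backend, `function(data, prior, mcmc)` returning a
#'   `vm_fit`-like object; defaults to [sample_posterior()]. Injectable so
#'   the harness can be validated against an exact-posterior stub.
#' @param sim_fn Data generator, `function(design)` returning
#'   `list(data, truth)`; defaults to [simulate_dataset()].
#' @param verbose Print a progress line every 25 replicates.
#' @return An object of class `vm_scenario_result`: list with `replicates`
#'   (one data.frame row per replicate), `aggregates` (means, empirical SEs,
#'   CI/PI coverages, each with a bootstrap 95% interval), `n_excluded` and
#'   the `scenario`.
#' @export
run_scenario <- function(sc, level = 0.95, rhat_threshold = 1.05,
                         n_boot = 10000, fit_fn = NULL, sim_fn = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(sc, "vm_scenario"))
  if (is.null(fit_fn)) fit_fn <- sample_posterior
  if (is.null(sim_fn)) sim_fn <- simulate_dataset
  root <- sc$design$seed
  mu_true <- sc$design$pop$mu
  sigma_true <- sc$design$pop$sigma

  rows <- vector("list", sc$n_sim)
  for (r in seq_len(sc$n_sim)) {
    des_r <- sc$design
    des_r$seed <- child_seed(root, r, 0L)
    mcmc_r <- sc$mcmc
    mcmc_r$seed <- child_seed(root, r, 1L)
    rec <- list(
      rep = r, seed = des_r$seed, mu_hat = NA_real_, sigma_hat = NA_real_,
      mu_lo = NA_real_, mu_hi = NA_real_, sigma_lo = NA_real_,
      sigma_hi = NA_real_, pi_lo = NA_real_, pi_hi = NA_real_,
      sigma_new = NA_real_, ci_cover_mu = NA, ci_cover_sigma = NA,
      pi_cover = NA, max_rhat = NA_real_, divergences = NA_integer_,
      converged = FALSE, error = NA_character_
    )
    res <- tryCatch(
      {
        sim <- sim_fn(des_r)
        fit <- suppressWarnings(fit_fn(sim$data, sc$prior, mcmc_r))
        mu_d <- as.vector(extract_draws(fit, "mu"))
        sigma_d <- as.vector(extract_draws(fit, "sigma"))
        set.seed(child_seed(root, r, 2L))
        S <- posterior_predictive_S(fit)
        sigma_new <- stats::rlnorm(1, mu_true, sigma_true)
        ci_mu <- credible_interval(fit, "mu", level)
        ci_sigma <- credible_interval(fit, "sigma", level)
        pi_S <- equal_tailed_interval(S, level)
        rh <- fit$diagnostics$rhat
        max_rhat <- if (all(is.na(rh))) NA_real_ else max(rh, na.rm = TRUE)
        list(
          mu_hat = mean(mu_d), sigma_hat = mean(sigma_d),
          mu_lo = ci_mu[1], mu_hi = ci_mu[2],
          sigma_lo = ci_sigma[1], sigma_hi = ci_sigma[2],
          pi_lo = pi_S[1], pi_hi = pi_S[2], sigma_new = sigma_new,
          ci_cover_mu = ci_mu[1] <= mu_true && mu_true <= ci_mu[2],
          ci_cover_sigma = ci_sigma[1] <= sigma_true && sigma_true <= ci_sigma[2],
          pi_cover = pi_S[1] <= sigma_new && sigma_new <= pi_S[2],
          max_rhat = max_rhat,
          divergences = sum(fit$divergences),
          converged = is.na(max_rhat) || max_rhat <= rhat_threshold
        )
      },
      error = function(e) list(error = conditionMessage(e))
    )
    rec[names(res)] <- res
    rows[[r]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    if (verbose && r %% 25 == 0) {
      message("replicate ", r, "/", sc$n_sim)
    }
  }
  reps <- do.call(rbind, rows)
  ok <- reps$converged & is.na(reps$error)
  n_excluded <- sum(!ok)
  agg <- NULL
  if (sum(ok) >= 2) {
    bseed <- child_seed(root, 0L, 3L)
    agg <- list(
      n_used = sum(ok),
      mean_mu_hat = mean(reps$mu_hat[ok]),
      mean_mu_hat_boot = bootstrap_interval(reps$mu_hat[ok], n_boot, seed = bseed),
      mean_sigma_hat = mean(reps$sigma_hat[ok]),
      mean_sigma_hat_boot = bootstrap_interval(reps$sigma_hat[ok], n_boot, seed = bseed + 1L),
      empirical_se_mu = empirical_se(reps$mu_hat[ok]),
      empirical_se_sigma = empirical_se(reps$sigma_hat[ok]),
      ci_coverage_mu = coverage(reps$ci_cover_mu[ok], n_boot, seed = bseed + 2L),
      ci_coverage_sigma = coverage(reps$ci_cover_sigma[ok], n_boot, seed = bseed + 3L),
      pi_coverage = coverage(reps$pi_cover[ok], n_boot, seed = bseed + 4L)
    )
  }
  structure(
    list(
      replicates = reps, aggregates = agg, n_excluded = n_excluded,
      scenario = sc
    ),
    class = "vm_scenario_result"
  )
}

#' @export
print.vm_scenario_result <- function(x, ...) {
  sc <- x$scenario
  cat(
    "<vm_scenario_result> ", sc$label, " n_sim=", sc$n_sim,
    " (excluded ", x$n_excluded, ")\n",
    sep = ""
  )
  a <- x$aggregates
  if (!is.null(a)) {
    cat(sprintf(
      "  mean mu_hat    %.4f [%.4f, %.4f]  emp SE %.4f\n",
      a$mean_mu_hat, a$mean_mu_hat_boot[1], a$mean_mu_hat_boot[2],
      a$empirical_se_mu
    ))
    cat(sprintf(
      "  mean sigma_hat %.4f [%.4f, %.4f]  emp SE %.4f\n",
      a$mean_sigma_hat, a$mean_sigma_hat_boot[1], a$mean_sigma_hat_boot[2],
      a$empirical_se_sigma
    ))
    cat(sprintf(
      "  CI coverage mu %.3f sigma %.3f   PI coverage %.3f\n",
      a$ci_coverage_mu$estimate, a$ci_coverage_sigma$estimate,
      a$pi_coverage$estimate
    ))
  }
  invisible(x)
}

#' Prior-sensitivity sweep
#'
#' Refits the model on the same dataset for a ladder of prior SDs (applied
#' to both population-parameter priors) and summarizes the posterior of
#' \eqn{\mu} and \eqn{\sigma} per setting. The reference analysis uses SDs
#' 1-5 and finds no material prior influence; the returned
#' `max_shift_mu` / `max_shift_sigma` attributes hold the maximum absolute
#' pairwise difference of the posterior means across settings.
#'
#' @param data A [vm_dataset()].
#' @param prior_sds Numeric vector of prior SDs (default `1:5`).
#' @param mcmc An [mcmc_config()]; the same seed is used for every refit.
#' @param product_mean_prior_sd Held fixed across the sweep (default 5).
#' @return A data.frame with one row per prior SD: posterior means, SDs and
#'   95% CIs of `mu` and `sigma`, plus attributes `max_shift_mu` and
#'   `max_shift_sigma`.
#' @export
prior_sensitivity <- function(data, prior_sds = 1:5, mcmc = mcmc_config(),
                              product_mean_prior_sd = 5) {
  stopifnot(length(prior_sds) >= 1, all(prior_sds > 0))
  rows <- lapply(prior_sds, function(s) {
    pr <- prior_config(
      mu_prior_sd = s, sigma_prior_sd = s,
      product_mean_prior_sd = product_mean_prior_sd
    )
    fit <- suppressWarnings(sample_posterior(data, pr, mcmc))
    mu_d <- as.vector(extract_draws(fit, "mu"))
    sg_d <- as.vector(extract_draws(fit, "sigma"))
    ci_mu <- credible_interval(fit, "mu")
    ci_sg <- credible_interval(fit, "sigma")
    data.frame(
      prior_sd = s,
      mu_mean = mean(mu_d), mu_sd = stats::sd(mu_d),
      mu_lo = ci_mu[1], mu_hi = ci_mu[2],
      sigma_mean = mean(sg_d), sigma_sd = stats::sd(sg_d),
      sigma_lo = ci_sg[1], sigma_hi = ci_sg[2]
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "max_shift_mu") <-
    if (nrow(out) > 1) max(stats::dist(out$mu_mean)) else 0
  attr(out, "max_shift_sigma") <-
    if (nrow(out) > 1) max(stats::dist(out$sigma_mean)) else 0
  out
}
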