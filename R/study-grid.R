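#' Study grid configuration
#'
#' Assembles the full simulation-study specification: the grid of
#' (products, batches, cycles, ratio) cells, the replication count, the
#' generating population and the prior/MCMC settings.
#'
#' Two preset modes are provided. `"paper"` is the full reference study:
#' every combination of \eqn{n_P \in \{5,7,10,15,25,50\}} and \eqn{n_b \in
#' \{3,5,7,10,15,25,50\}} at `n_sim = 1000` (cluster-scale). `"desk"` is a
#' laptop-scale subset: \eqn{n_P \in \{5,15,50\} \times n_b \in \{3,10,50\}}
#' at `n_sim = 200`.
#'
#' @param mode `"desk"` (default) or `"paper"`.
#' @param grid Optional data.frame overriding the preset grid; columns
#'   `n_products`, `n_batches` and optionally `n_cycles`, `tau_nu_ratio`.
#' @param n_sim Optional override of the per-cell replication count.
#' @param pop Generating [population_params()] (default (0.1, 0.4)).
#' @param prior A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param seed Root seed of the whole study.
#' @return An object of class `vm_study_config`.
#' @export
study_config <- function(mode = c("desk", "paper"), grid = NULL, n_sim = NULL,
                         pop = population_params(0.1, 0.4),
                         prior = prior_config(), mcmc = mcmc_config(),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(grid)) {
    np <- if (mode == "paper") c(5, 7, 10, 15, 25, 50) else c(5, 15, 50)
    nb <- if (mode == "paper") c(3, 5, 7, 10, 15, 25, 50) else c(3, 10, 50)
    grid <- expand.grid(n_products = np, n_batches = nb)
  }
  grid <- as.data.frame(grid)
  stopifnot(all(c("n_products", "n_batches") %in% names(grid)))
  if (!"n_cycles" %in% names(grid)) grid$n_cycles <- 1L
  if (!"tau_nu_ratio" %in% names(grid)) grid$tau_nu_ratio <- NA_real_
  if (is.null(n_sim)) n_sim <- if (mode == "paper") 1000L else 200L
  structure(
    list(
      mode = mode, grid = grid, n_sim = as.integer(n_sim), pop = pop,
      prior = prior, mcmc = mcmc, seed = as.integer(seed)
    ),
    class = "vm_study_config"
  )
}

#' Run a full simulation study over a grid of scenarios
#'
#' Executes [run_scenario()] for every grid cell and assembles a plot-ready
#' aggregate table (mean estimates vs `n_products` by `n_batches`, coverage
#' vs sample size, and estimate/coverage vs the \eqn{\tau_i/\nu_i} ratio for
#' multi-cycle cells).
#'
#' @param cfg A [study_config()].
#' @param n_boot Bootstrap resamples for aggregate intervals.
#' @param verbose Report per-cell progress.
#' @return An object of class `vm_study_result`: list with `results` (one
#'   [run_scenario()] result per cell), `table` (aggregate data.frame) and
#'   the `config`.
#' @export
run_study <- function(cfg, n_boot = 10000, verbose = FALSE) {
  stopifnot(inherits(cfg, "vm_study_config"))
  g <- cfg$grid
  results <- vector("list", nrow(g))
  rows <- vector("list", nrow(g))
  for (k in seq_len(nrow(g))) {
    ratio <- g$tau_nu_ratio[k]
    des <- simulation_design(
      n_products = g$n_products[k], n_batches = g$n_batches[k],
      n_cycles = g$n_cycles[k], pop = cfg$pop,
      tau_nu_ratio = if (g$n_cycles[k] > 1) ratio else NULL,
      seed = child_seed(cfg$seed, k, 9L)
    )
    lab <- sprintf(
      "nP=%d nb=%d nc=%d%s", g$n_products[k], g$n_batches[k], g$n_cycles[k],
      if (!is.na(ratio)) sprintf(" ratio=%.3g", ratio) else ""
    )
    if (verbose) message("cell ", k, "/", nrow(g), ": ", lab)
    res <- run_scenario(
      scenario(des, cfg$prior, cfg$mcmc, n_sim = cfg$n_sim, label = lab),
      n_boot = n_boot, verbose = FALSE
    )
    results[[k]] <- res
    a <- res$aggregates
    rows[[k]] <- data.frame(
      n_products = g$n_products[k], n_batches = g$n_batches[k],
      n_cycles = g$n_cycles[k], tau_nu_ratio = ratio,
      n_sim = cfg$n_sim, n_excluded = res$n_excluded,
      mean_mu_hat = a$mean_mu_hat,
      mu_boot_lo = a$mean_mu_hat_boot[1], mu_boot_hi = a$mean_mu_hat_boot[2],
      mean_sigma_hat = a$mean_sigma_hat,
      sigma_boot_lo = a$mean_sigma_hat_boot[1],
      sigma_boot_hi = a$mean_sigma_hat_boot[2],
      empirical_se_mu = a$empirical_se_mu,
      empirical_se_sigma = a$empirical_se_sigma,
      ci_coverage_mu = a$ci_coverage_mu$estimate,
      ci_cov_mu_lo = a$ci_coverage_mu$interval[1],
      ci_cov_mu_hi = a$ci_coverage_mu$interval[2],
      ci_coverage_sigma = a$ci_coverage_sigma$estimate,
      ci_cov_sigma_lo = a$ci_coverage_sigma$interval[1],
      ci_cov_sigma_hi = a$ci_coverage_sigma$interval[2],
      pi_coverage = a$pi_coverage$estimate,
      pi_cov_lo = a$pi_coverage$interval[1],
      pi_cov_hi = a$pi_coverage$interval[2]
    )
  }
  structure(
    list(results = results, table = do.call(rbind, rows), config = cfg),
    class = "vm_study_result"
  )
}
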