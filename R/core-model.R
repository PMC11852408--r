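#' Population parameters of the random-variance model
#'
#' The model treats each product's total standard deviation \eqn{\sigma_i} as
#' a random effect with \eqn{\ln(\sigma_i) \sim N(\mu, \sigma)}. `mu` and
#' `sigma` are therefore the location and scale of the lognormal population
#' of product SDs, on the log-SD scale; they are the parameters of interest
#' of the meta-analysis.
#'
#' @param mu Location of \eqn{\ln \sigma_i}.
#' @param sigma Scale of \eqn{\ln \sigma_i}; must be non-negative.
#'   `sigma = 0` denotes the degenerate population (all products share
#'   \eqn{\sigma_i = e^\mu}); it is accepted by the simulator but rejected by
#'   the density functions, which require `sigma > 0`.
#' @return An object of class `vm_population_params`.
#' @export
population_params <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  stopifnot(is.numeric(sigma), length(sigma) == 1, is.finite(sigma))
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(mu = mu, sigma = sigma), class = "vm_population_params")
}

#' Prior configuration
#'
#' Weakly informative priors: \eqn{\mu \sim N(0, s_\mu)}, a half-normal
#' \eqn{\sigma \sim N^+(0, s_\sigma)} for the population scale (the positive
#' truncation of the stated standard-normal prior), independent
#' \eqn{\mu_i \sim N(0, s_{pm})} for the product means, and a fixed
#' Uniform(0, 1) prior on the between-batch variance proportion
#' \eqn{p_i = \tau_i^2 / \sigma_i^2} of each multi-cycle product.
#'
#' @param mu_prior_sd Prior SD of the population location (default 1).
#' @param sigma_prior_sd Prior SD of the half-normal on the population scale
#'   (default 1).
#' @param product_mean_prior_sd Prior SD of the product means (default 5;
#'   appropriate for data centered near zero — center real data first).
#' @return An object of class `vm_prior`.
#' @export
prior_config <- function(mu_prior_sd = 1, sigma_prior_sd = 1,
                         product_mean_prior_sd = 5) {
  sds <- c(mu_prior_sd, sigma_prior_sd, product_mean_prior_sd)
  if (!all(is.finite(sds)) || any(sds <= 0)) stop("all prior SDs must be > 0")
  structure(
    list(
      mu_prior_sd = mu_prior_sd,
      sigma_prior_sd = sigma_prior_sd,
      product_mean_prior_sd = product_mean_prior_sd
    ),
    class = "vm_prior"
  )
}

#' Per-product effects
#'
#' A product is described by its fixed-effect mean `mu_i` and its total SD
#' `sigma_i` (the random effect). Multi-cycle products additionally split the
#' total variance into a between-batch component \eqn{\tau_i^2} and a
#' within-batch (residual) component \eqn{\nu_i^2} with
#' \eqn{\sigma_i^2 = \tau_i^2 + \nu_i^2}. The split can be given either as
#' `(tau_i, nu_i)` — checked against `sigma_i` to relative tolerance 1e-10 —
#' or as the proportion `p_i` = \eqn{\tau_i^2/\sigma_i^2}, from which the
#' components are derived exactly.
#'
#' @param mu_i Product mean (fixed effect).
#' @param sigma_i Total product SD; must be > 0.
#' @param tau_i,nu_i Optional between-batch and within-batch SDs.
#' @param p_i Optional between-batch variance proportion in \[0, 1\].
#' @return An object of class `vm_product_effects` with fields `mu_i`,
#'   `sigma_i` and, when a split is present, `tau_i`, `nu_i`, `p_i`.
#' @export
product_effects <- function(mu_i, sigma_i, tau_i = NULL, nu_i = NULL,
                            p_i = NULL) {
  stopifnot(is.finite(mu_i), is.finite(sigma_i))
  if (sigma_i <= 0) stop("`sigma_i` must be > 0")
  out <- list(mu_i = mu_i, sigma_i = sigma_i)
  if (!is.null(p_i)) {
    if (!is.null(tau_i) || !is.null(nu_i)) {
      stop("give either `p_i` or (`tau_i`, `nu_i`), not both")
    }
    if (!is.finite(p_i) || p_i < 0 || p_i > 1) stop("`p_i` must be in [0, 1]")
    tau_i <- sigma_i * sqrt(p_i)
    nu_i <- sigma_i * sqrt(1 - p_i)
  }
  if (!is.null(tau_i) || !is.null(nu_i)) {
    if (is.null(tau_i) || is.null(nu_i)) {
      stop("`tau_i` and `nu_i` must be given together")
    }
    if (tau_i < 0 || nu_i < 0) stop("`tau_i` and `nu_i` must be >= 0")
    if (abs(tau_i^2 + nu_i^2 - sigma_i^2) > 1e-10 * sigma_i^2) {
      stop("sigma_i^2 = tau_i^2 + nu_i^2 violated beyond relative 1e-10")
    }
    out$tau_i <- tau_i
    out$nu_i <- nu_i
    out$p_i <- tau_i^2 / sigma_i^2
  }
  structure(out, class = "vm_product_effects")
}

#' Latent batch means of a multi-cycle product
#'
#' @param mu_ij Numeric vector of batch means \eqn{\mu_{ij} \sim N(\mu_i,
#'   \tau_i)}, one entry per batch, in batch order.
#' @return An object of class `vm_batch_effects`.
#' @export
batch_effects <- function(mu_ij) {
  stopifnot(is.numeric(mu_ij), all(is.finite(mu_ij)))
  structure(list(mu_ij = as.numeric(mu_ij)), class = "vm_batch_effects")
}

.half_normal_logpdf <- function(x, sd) {
  if (x <= 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, sd, log = TRUE)
}

#' Joint log prior
#'
#' Sum of the log prior densities of the population parameters, all product
#' means, and the variance-split proportions of multi-cycle products:
#' \eqn{\log N(\mu \mid 0, s_\mu) + \log N^+(\sigma \mid 0, s_\sigma) +
#' \sum_i \log N(\mu_i \mid 0, s_{pm}) + \sum_i \log U(p_i \mid 0, 1)}.
#'
#' @param pop A [population_params()] object; `pop$sigma` must be > 0.
#' @param effects List of [product_effects()] objects (may be empty).
#' @param prior A [prior_config()] object.
#' @return The log prior density (finite for interior parameter values).
#' @export
log_prior <- function(pop, effects = list(), prior = prior_config()) {
  if (pop$sigma <= 0) stop("`pop$sigma` must be > 0 in the prior density")
  lp <- stats::dnorm(pop$mu, 0, prior$mu_prior_sd, log = TRUE) +
    .half_normal_logpdf(pop$sigma, prior$sigma_prior_sd)
  for (eff in effects) {
    lp <- lp + stats::dnorm(eff$mu_i, 0, prior$product_mean_prior_sd, log = TRUE)
    if (!is.null(eff$p_i)) {
      lp <- lp + stats::dunif(eff$p_i, 0, 1, log = TRUE)
    }
  }
  lp
}

#' Single-cycle log likelihood of one product
#'
#' \eqn{\sum_j \log N(y_{ij} \mid \mu_i, \sigma_i)} over the product's batch
#' values.
#'
#' @param y Numeric vector of batch measurements \eqn{y_{ij}}.
#' @param eff A [product_effects()] object.
#' @return The log likelihood.
#' @export
loglik_single_cycle <- function(y, eff) {
  y <- as.numeric(y)
  if (length(y) == 0) stop("empty batch value vector")
  if (eff$sigma_i <= 0) stop("`sigma_i` must be > 0")
  sum(stats::dnorm(y, eff$mu_i, eff$sigma_i, log = TRUE))
}

#' Multi-cycle log likelihood of one product
#'
#' Hierarchical likelihood of nested batch/cycle data:
#' \eqn{\sum_j \log N(\mu_{ij} \mid \mu_i, \tau_i) + \sum_j \sum_k
#' \log N(y_{ijk} \mid \mu_{ij}, \nu_i)}.
#'
#' @param batches List of numeric vectors, one per batch, holding cycle
#'   values \eqn{y_{ijk}}.
#' @param eff A [product_effects()] object carrying a variance split with
#'   `tau_i > 0` and `nu_i > 0` (boundary values are excluded; the sampler
#'   works on the logit scale of `p_i` and never evaluates them).
#' @param bmeans A [batch_effects()] object (or bare numeric vector) with
#'   one batch mean per element of `batches`.
#' @return The log likelihood.
#' @export
loglik_multi_cycle <- function(batches, eff, bmeans) {
  if (length(batches) == 0) stop("empty batch list")
  if (is.null(eff$tau_i) || is.null(eff$nu_i)) {
    stop("`eff` must carry a (tau_i, nu_i) split for a multi-cycle product")
  }
  if (eff$tau_i <= 0 || eff$nu_i <= 0) stop("`tau_i` and `nu_i` must be > 0")
  mu_ij <- if (inherits(bmeans, "vm_batch_effects")) bmeans$mu_ij else as.numeric(bmeans)
  if (length(mu_ij) != length(batches)) {
    stop("need exactly one batch mean per batch")
  }
  ll <- sum(stats::dnorm(mu_ij, eff$mu_i, eff$tau_i, log = TRUE))
  for (j in seq_along(batches)) {
    ll <- ll + sum(stats::dnorm(as.numeric(batches[[j]]), mu_ij[j], eff$nu_i, log = TRUE))
  }
  ll
}

#' Random-effect log density of a product SD
#'
#' Lognormal log density of the total product SD with respect to
#' \eqn{\sigma_i} itself: \eqn{\log N(\ln \sigma_i \mid \mu, \sigma) -
#' \ln \sigma_i} (the Jacobian of the log transform is included, so
#' `exp(log_random_effect)` integrates to 1 over \eqn{\sigma_i \in (0,
#' \infty)}).
#'
#' @param eff A [product_effects()] object (`sigma_i > 0`).
#' @param pop A [population_params()] object (`sigma > 0`).
#' @return The log density.
#' @export
log_random_effect <- function(eff, pop) {
  if (eff$sigma_i <= 0) stop("`sigma_i` must be > 0")
  if (pop$sigma <= 0) stop("`pop$sigma` must be > 0")
  stats::dlnorm(eff$sigma_i, meanlog = pop$mu, sdlog = pop$sigma, log = TRUE)
}

#' Unnormalized joint log posterior
#'
#' Exact additive assembly of the model's joint log density:
#' `log_prior + sum(log_random_effect) + sum(per-product log likelihood)`,
#' with the single- or multi-cycle likelihood selected by each product's
#' mode.
#'
#' @param data A [vm_dataset()].
#' @param pop A [population_params()] object.
#' @param effects Named list of [product_effects()], one per product
#'   (names = product labels).
#' @param batch_means Named list of [batch_effects()] for the multi-cycle
#'   products (names = product labels); must not contain entries for
#'   single-cycle products.
#' @param prior A [prior_config()] object.
#' @return The unnormalized log posterior density.
#' @export
log_posterior_unnormalized <- function(data, pop, effects,
                                       batch_means = list(),
                                       prior = prior_config()) {
  modes <- product_mode(data)
  ids <- names(modes)
  if (!setequal(names(effects), ids)) {
    stop("`effects` must contain exactly one entry per product")
  }
  extra <- setdiff(names(batch_means), ids[modes == "multi_cycle"])
  if (length(extra) > 0) {
    stop("batch means supplied for non-multi-cycle product(s): ",
         paste(extra, collapse = ", "))
  }
  lp <- log_prior(pop, effects[ids], prior)
  for (id in ids) {
    eff <- effects[[id]]
    lp <- lp + log_random_effect(eff, pop)
    if (modes[[id]] == "single_cycle") {
      if (!is.null(eff$tau_i)) {
        stop("multi-cycle parameters supplied for single-cycle product: ", id)
      }
      lp <- lp + loglik_single_cycle(product_data(data, id), eff)
    } else {
      bm <- batch_means[[id]]
      if (is.null(bm)) stop("missing batch means for multi-cycle product: ", id)
      lp <- lp + loglik_multi_cycle(product_data(data, id), eff, bm)
    }
  }
  lp
}
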