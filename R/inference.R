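#' MCMC sampler configuration
#'
#' Defaults follow the reference analysis: two chains of 5000 iterations
#' including 1000 discarded warmup draws, thinning factor 2 (every second
#' post-warmup draw kept), target acceptance 0.95, initial step size 0.05
#' (adapted during warmup), maximum tree depth 15. The default configuration
#' retains `2 * (5000 - 1000) / 2 = 4000` draws.
#'
#' @param n_chains Number of chains (default 2).
#' @param n_iterations Iterations per chain, including warmup (default 5000).
#' @param n_warmup Warmup iterations discarded per chain (default 1000).
#' @param thin Thinning factor (default 2).
#' @param target_accept Target mean acceptance statistic (default 0.95).
#' @param init_step_size Initial leapfrog step size before adaptation
#'   (default 0.05).
#' @param max_tree_depth Maximum NUTS doubling depth (default 15).
#' @param seed Integer RNG seed.
#' @return An object of class `vm_mcmc`.
#' @export
mcmc_config <- function(n_chains = 2, n_iterations = 5000, n_warmup = 1000,
                        thin = 2, target_accept = 0.95, init_step_size = 0.05,
                        max_tree_depth = 15, seed = 1L) {
  stopifnot(n_chains >= 1, n_iterations >= 2, thin >= 1)
  if (n_warmup >= n_iterations) stop("`n_warmup` must be < `n_iterations`")
  if (target_accept <= 0 || target_accept >= 1) stop("`target_accept` in (0,1)")
  if (init_step_size <= 0) stop("`init_step_size` must be > 0")
  structure(
    list(
      n_chains = as.integer(n_chains), n_iterations = as.integer(n_iterations),
      n_warmup = as.integer(n_warmup), thin = as.integer(thin),
      target_accept = target_accept, init_step_size = init_step_size,
      max_tree_depth = as.integer(max_tree_depth), seed = as.integer(seed)
    ),
    class = "vm_mcmc"
  )
}

#' @rdname mcmc_config
#' @param cfg A `vm_mcmc` object.
#' @export
n_retained_draws <- function(cfg) {
  cfg$n_chains * ((cfg$n_iterations - cfg$n_warmup) %/% cfg$thin)
}

# Compact per-batch sufficient statistics handed to the compiled density.
.vm_model_data <- function(data) {
  modes <- product_mode(data)
  ids <- names(modes)
  P <- length(ids)
  sc_n <- sc_sum <- sc_ss <- numeric(P)
  bptr <- integer(P + 1)
  b_n <- b_sum <- b_ss <- numeric(0)
  batch_labels <- stats::setNames(vector("list", P), ids)
  for (i in seq_len(P)) {
    pd <- product_data(data, ids[i])
    if (modes[[i]] == "single_cycle") {
      sc_n[i] <- length(pd)
      sc_sum[i] <- sum(pd)
      sc_ss[i] <- sum(pd^2)
      bptr[i + 1] <- bptr[i]
    } else {
      bptr[i + 1] <- bptr[i] + length(pd)
      b_n <- c(b_n, lengths(pd))
      b_sum <- c(b_sum, vapply(pd, sum, numeric(1)))
      b_ss <- c(b_ss, vapply(pd, function(v) sum(v^2), numeric(1)))
      batch_labels[[ids[i]]] <- names(pd)
    }
  }
  list(
    modes = as.integer(modes == "multi_cycle"),
    sc_n = sc_n, sc_sum = sc_sum, sc_ss = sc_ss,
    bptr = bptr, b_n = b_n, b_sum = b_sum, b_ss = b_ss,
    ids = ids, batch_labels = batch_labels
  )
}

# Constrained parameter names in unconstrained-layout order.
.vm_param_names <- function(md) {
  ids <- md$ids
  multi <- ids[md$modes == 1]
  c(
    "mu", "sigma",
    paste0("mu_i[", ids, "]"), paste0("sigma_i[", ids, "]"),
    if (length(multi)) paste0("p_i[", multi, "]"),
    unlist(lapply(multi, function(id) {
      paste0("mu_ij[", id, ",", md$batch_labels[[id]], "]")
    }), use.names = FALSE)
  )
}

# unconstrained draw array (keep x chains x D) -> constrained, same shape
.vm_constrain <- function(a, md) {
  P <- length(md$ids)
  multi <- which(md$modes == 1)
  out <- a
  out[, , 2] <- exp(a[, , 2]) # sigma
  lam_off <- 2 + P
  # product SDs from the non-centered deviates: ln sigma_i = mu + sigma * u_i
  for (i in seq_len(P)) {
    out[, , lam_off + i] <- exp(a[, , 1] + out[, , 2] * a[, , lam_off + i])
  }
  pos <- 2 + 2 * P
  q_of <- integer(P)
  for (i in multi) {
    pos <- pos + 1
    q_of[i] <- pos
    out[, , pos] <- stats::plogis(a[, , pos])
  }
  for (i in multi) {
    nb <- md$bptr[i + 1] - md$bptr[i]
    sig_i <- out[, , lam_off + i]
    tau_i <- sig_i * sqrt(out[, , q_of[i]])
    for (j in seq_len(nb)) {
      pos <- pos + 1
      out[, , pos] <- a[, , 2 + i] + tau_i * a[, , pos]
    }
  }
  out
}

#' Sample the posterior of the random-variance model
#'
#' Draws from the joint posterior of all model parameters with a built-in
#' no-U-turn sampler (adaptive Hamiltonian Monte Carlo with dual-averaging
#' step-size adaptation and a diagonal mass matrix estimated during warmup).
#' Sampling is performed on an unconstrained scale: log for the scale
#' parameters \eqn{\sigma} and \eqn{\sigma_i}, logit for the variance
#' proportions \eqn{p_i}, and non-centered batch means
#' \eqn{\mu_{ij} = \mu_i + \tau_i z_{ij}}. Retained draws are reported on
#' the constrained (natural) scale.
#'
#' @param data A [vm_dataset()].
#' @param prior A [prior_config()].
#' @param cfg An [mcmc_config()].
#' @return An object of class `vm_fit`: list with `draws` (array
#'   iterations x chains x parameters, constrained scale), `diagnostics`
#'   (data.frame with per-parameter split R-hat and effective sample size),
#'   `divergences`, `treedepth_hits`, `step_sizes`, `accept_stats` (per
#'   chain), and the resolved `prior`/`config`. A warning is raised when any
#'   parameter has split R-hat above 1.05 or post-warmup divergences
#'   occurred.
#' @export
sample_posterior <- function(data, prior = prior_config(), cfg = mcmc_config()) {
  stopifnot(inherits(data, "vm_dataset"))
  stopifnot(inherits(prior, "vm_prior"), inherits(cfg, "vm_mcmc"))
  modes <- product_mode(data)
  for (id in names(modes)) {
    if (modes[[id]] == "single_cycle" && length(product_data(data, id)) == 1) {
      warning(
        "product '", id, "' has a single observation; its sigma_i is ",
        "informed almost entirely by the population distribution"
      )
    }
  }
  md <- .vm_model_data(data)
  D <- 2L + 2L * length(md$ids) + sum(md$modes == 1) + length(md$b_n)
  set.seed(cfg$seed)
  theta0 <- matrix(stats::runif(D * cfg$n_chains, -2, 2), nrow = D)
  raw <- vm_nuts(
    md, unclass(prior), theta0, cfg$n_iterations, cfg$n_warmup, cfg$thin,
    cfg$target_accept, cfg$init_step_size, cfg$max_tree_depth
  )
  a <- .vm_constrain(raw$draws, md)
  pn <- .vm_param_names(md)
  dimnames(a) <- list(NULL, paste0("chain", seq_len(cfg$n_chains)), pn)
  diag_df <- data.frame(
    parameter = pn,
    rhat = vapply(seq_along(pn), function(d) {
      m <- a[, , d, drop = FALSE]
      dim(m) <- dim(m)[1:2]
      if (cfg$n_chains >= 2) suppressWarnings(rhat(m)) else NA_real_
    }, numeric(1)),
    ess = vapply(seq_along(pn), function(d) {
      m <- a[, , d, drop = FALSE]
      dim(m) <- dim(m)[1:2]
      # 200 lags are ample for thinned NUTS chains; keeps per-fit cost low
      suppressWarnings(effective_sample_size(m, max_lag = min(nrow(m) - 1, 200)))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  fit <- structure(
    list(
      draws = a, diagnostics = diag_df,
      divergences = as.integer(raw$divergences),
      treedepth_hits = as.integer(raw$treedepth_hits),
      step_sizes = as.numeric(raw$step_sizes),
      accept_stats = as.numeric(raw$accept_stats),
      prior = prior, config = cfg, model_data = md
    ),
    class = "vm_fit"
  )
  bad <- diag_df$parameter[!is.na(diag_df$rhat) & diag_df$rhat > 1.05]
  if (length(bad) > 0) {
    warning(
      "possible non-convergence: split R-hat > 1.05 for ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  if (sum(fit$divergences) > 0) {
    warning(sum(fit$divergences), " divergent transition(s) after warmup")
  }
  fit
}

#' Extract the draws of one parameter
#'
#' @param fit A `vm_fit`.
#' @param param Parameter name (e.g. `"mu"`, `"sigma"`, `"sigma_i[P01]"`).
#' @return Numeric matrix, iterations x chains.
#' @export
extract_draws <- function(fit, param) {
  pn <- dimnames(fit$draws)[[3]]
  if (!param %in% pn) stop("unknown parameter: ", param)
  m <- fit$draws[, , param, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' @export
print.vm_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(
    "<vm_fit> ", d[1] * d[2], " retained draws (", d[1], " x ", d[2],
    " chains), ", d[3], " parameters\n",
    sep = ""
  )
  core <- x$diagnostics[x$diagnostics$parameter %in% c("mu", "sigma"), ]
  for (k in seq_len(nrow(core))) {
    dr <- extract_draws(x, core$parameter[k])
    cat(sprintf(
      "  %-6s mean %.4f sd %.4f  rhat %.3f  ess %.0f\n",
      core$parameter[k], mean(dr), stats::sd(dr), core$rhat[k], core$ess[k]
    ))
  }
  cat(
    "  divergences:", sum(x$divergences),
    " treedepth saturations:", sum(x$treedepth_hits), "\n"
  )
  invisible(x)
}
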