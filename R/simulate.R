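#' Simulation design
#'
#' Describes one synthetic-data scenario. The generative process matches the
#' model: product SDs are drawn from the lognormal population
#' \eqn{\ln(\sigma_i) \sim N(\mu, \sigma)}; with `n_cycles = 1` batch values
#' are drawn directly as \eqn{y_{ij} \sim N(\mu_i, \sigma_i)} (single-cycle
#' path), otherwise each total SD is split into between-batch and
#' within-batch components at the fixed ratio \eqn{\tau_i/\nu_i}, batch means
#' \eqn{\mu_{ij} \sim N(\mu_i, \tau_i)} are sampled, and cycle values follow
#' \eqn{y_{ijk} \sim N(\mu_{ij}, \nu_i)} (multi-cycle path).
#'
#' @param n_products Number of products \eqn{n_P} (>= 1).
#' @param n_batches Number of batches per product \eqn{n_b} (>= 1).
#' @param n_cycles Cycles per batch \eqn{n_c} (>= 1); 1 selects the
#'   single-cycle path.
#' @param pop [population_params()]; defaults to the reference population
#'   \eqn{(\mu, \sigma) = (0.1, 0.4)}.
#' @param tau_nu_ratio Ratio \eqn{\tau_i/\nu_i} (> 0); required iff
#'   `n_cycles > 1`, applied identically to every product.
#' @param product_means Fixed-effect product means \eqn{\mu_i}; scalar 0 by
#'   default, recycled to `n_products`.
#' @param seed Integer RNG seed.
#' @return An object of class `vm_design`.
#' @export
simulation_design <- function(n_products, n_batches, n_cycles = 1,
                              pop = population_params(0.1, 0.4),
                              tau_nu_ratio = NULL, product_means = 0,
                              seed = 1L) {
  stopifnot(n_products >= 1, n_batches >= 1, n_cycles >= 1)
  stopifnot(inherits(pop, "vm_population_params"))
  if (n_cycles > 1) {
    if (is.null(tau_nu_ratio)) stop("`tau_nu_ratio` is required when n_cycles > 1")
    if (!is.finite(tau_nu_ratio) || tau_nu_ratio <= 0) {
      stop("`tau_nu_ratio` must be > 0")
    }
  } else if (!is.null(tau_nu_ratio)) {
    stop("`tau_nu_ratio` only applies when n_cycles > 1")
  }
  product_means <- rep_len(as.numeric(product_means), n_products)
  structure(
    list(
      n_products = as.integer(n_products), n_batches = as.integer(n_batches),
      n_cycles = as.integer(n_cycles), pop = pop,
      tau_nu_ratio = tau_nu_ratio, product_means = product_means,
      seed = as.integer(seed)
    ),
    class = "vm_design"
  )
}

#' Draw product SDs from the lognormal population
#'
#' \eqn{\sigma_i = \exp(\mu + \sigma z_i)}, \eqn{z_i} iid standard normal.
#'
#' @param pop A [population_params()] object (`sigma >= 0`; `sigma = 0`
#'   yields the degenerate draw \eqn{e^\mu}).
#' @param n_products Number of draws.
#' @return Numeric vector of positive product SDs.
#' @export
draw_product_sds <- function(pop, n_products) {
  stopifnot(n_products >= 1)
  stats::rlnorm(n_products, meanlog = pop$mu, sdlog = pop$sigma)
}

#' Split a total SD into between- and within-batch components
#'
#' Solves \eqn{\tau_i^2 + \nu_i^2 = \sigma_i^2} and \eqn{\tau_i/\nu_i =}
#' `ratio` exactly: \eqn{\nu_i = \sigma_i / \sqrt{1 + \mathrm{ratio}^2}},
#' \eqn{\tau_i = \mathrm{ratio} \cdot \nu_i}.
#'
#' @param sigma_i Total SD(s), > 0 (vectorized).
#' @param ratio Target \eqn{\tau_i/\nu_i}, > 0.
#' @return List with numeric components `tau_i` and `nu_i`.
#' @export
split_total_sd <- function(sigma_i, ratio) {
  if (any(!is.finite(sigma_i)) || any(sigma_i <= 0)) stop("`sigma_i` must be > 0")
  if (!is.finite(ratio) || ratio <= 0) stop("`ratio` must be > 0")
  nu_i <- sigma_i / sqrt(1 + ratio^2)
  list(tau_i = ratio * nu_i, nu_i = nu_i)
}

#' Derive a child RNG seed from a root seed
#'
#' Counter-based scheme used by the study harness so that replicate `rep`
#' of stream `stream` always sees the same seed regardless of execution
#' order. Results stay within the 32-bit signed-integer range.
#'
#' @param root Root integer seed.
#' @param rep Replicate counter (>= 0).
#' @param stream Sub-stream counter (>= 0); 0 = data generation,
#'   1 = sampler, 2 = predictive/new-product draws.
#' @return A positive integer seed.
#' @export
child_seed <- function(root, rep = 0L, stream = 0L) {
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(root)) %% m + as.numeric(rep) * 10007 +
    as.numeric(stream) * 104729) %% m
  as.integer(s) + 1L
}

#' Simulate a hierarchical dataset from a design
#'
#' Runs the generative process of the design and returns both the dataset
#' and all latent truths (for recovery testing). The same design (including
#' its seed) always reproduces the identical dataset.
#'
#' @param design A [simulation_design()].
#' @return List with elements `data` (a [vm_dataset()]) and `truth` (list:
#'   `sigma_i`, and for multi-cycle designs `tau_i`, `nu_i` and the matrix
#'   `mu_ij` of batch means; plus the generating `pop` and `product_means`).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "vm_design"))
  set.seed(design$seed)
  nP <- design$n_products
  nb <- design$n_batches
  nc <- design$n_cycles
  pid <- sprintf("P%02d", seq_len(nP))
  bid <- sprintf("B%02d", seq_len(nb))
  sigma_i <- draw_product_sds(design$pop, nP)
  truth <- list(
    sigma_i = stats::setNames(sigma_i, pid),
    pop = design$pop, product_means = stats::setNames(design$product_means, pid)
  )
  if (nc == 1) {
    y <- stats::rnorm(nP * nb,
      mean = rep(design$product_means, each = nb),
      sd = rep(sigma_i, each = nb)
    )
    df <- data.frame(
      product = rep(pid, each = nb), batch = rep(bid, times = nP),
      cycle = NA_character_, value = y
    )
  } else {
    split <- split_total_sd(sigma_i, design$tau_nu_ratio)
    truth$tau_i <- stats::setNames(split$tau_i, pid)
    truth$nu_i <- stats::setNames(split$nu_i, pid)
    mu_ij <- matrix(
      stats::rnorm(nP * nb,
        mean = rep(design$product_means, each = nb),
        sd = rep(split$tau_i, each = nb)
      ),
      nrow = nP, byrow = TRUE, dimnames = list(pid, bid)
    )
    truth$mu_ij <- mu_ij
    y <- stats::rnorm(nP * nb * nc,
      mean = rep(as.vector(t(mu_ij)), each = nc),
      sd = rep(split$nu_i, each = nb * nc)
    )
    cid <- sprintf("C%02d", seq_len(nc))
    df <- data.frame(
      product = rep(pid, each = nb * nc),
      batch = rep(rep(bid, each = nc), times = nP),
      cycle = rep(cid, times = nP * nb), value = y
    )
  }
  list(data = vm_dataset(df), truth = truth)
}
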