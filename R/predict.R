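#' Posterior predictive draws of a future product's total SD
#'
#' Integrates the lognormal population model over the joint posterior of
#' \eqn{(\mu, \sigma)}: for each retained posterior draw
#' \eqn{(\mu_d, \sigma_d)} one future-product SD is generated as
#' \eqn{S_d = \exp(\mu_d + \sigma_d z_d)}, \eqn{z_d \sim N(0,1)}. The
#' resulting sample is marginally distributed as the posterior predictive
#' distribution \eqn{p(S \mid Y)}.
#'
#' @param fit A `vm_fit` (or any list with a `draws` array containing
#'   parameters `"mu"` and `"sigma"`).
#' @param n_per_draw Number of predictive draws per posterior draw
#'   (default 1).
#' @return Object of class `vm_predictive`: numeric vector of positive
#'   predictive SD draws. Squared values give the predictive distribution of
#'   the future total variance \eqn{S^2}.
#' @export
posterior_predictive_S <- function(fit, n_per_draw = 1) {
  mu <- as.vector(extract_draws(fit, "mu"))
  sigma <- as.vector(extract_draws(fit, "sigma"))
  stopifnot(n_per_draw >= 1)
  mu <- rep(mu, times = n_per_draw)
  sigma <- rep(sigma, times = n_per_draw)
  s <- exp(mu + sigma * stats::rnorm(length(mu)))
  structure(s, class = "vm_predictive")
}

#' Equal-tailed credible interval of a parameter
#'
#' Quantile interval at probabilities \eqn{(1-\mathrm{level})/2} and
#' \eqn{1-(1-\mathrm{level})/2} of the pooled retained draws.
#'
#' @param fit A `vm_fit`.
#' @param param Parameter name.
#' @param level Interval mass in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(fit, param, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  x <- as.vector(extract_draws(fit, param))
  a <- (1 - level) / 2
  unname(stats::quantile(x, c(a, 1 - a)))
}

#' Equal-tailed interval of a draw vector
#'
#' Same convention as [credible_interval()] but for a bare sample, e.g. the
#' predictive draws of S.
#'
#' @param x Numeric vector of draws.
#' @param level Interval mass in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
equal_tailed_interval <- function(x, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  a <- (1 - level) / 2
  unname(stats::quantile(as.numeric(x), c(a, 1 - a)))
}
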