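#' Split Gelman-Rubin statistic (split R-hat)
#'
#' Each chain is split in half before the between/within-chain variance
#' comparison, so within-chain trends register as apparent non-mixing.
#' Values near 1 indicate that all (half-)chains target the same stationary
#' distribution; values above ~1.05 indicate non-convergence.
#'
#' @param chains Draws, as an iterations x chains matrix (or a list of
#'   equal-length numeric vectors). At least 2 chains of at least 4 draws.
#' @return The split R-hat; `NaN` with a warning when every chain has zero
#'   within-chain variance.
#' @export
rhat <- function(chains) {
  x <- .as_chain_matrix(chains)
  if (ncol(x) < 2) stop("need at least 2 chains")
  if (nrow(x) < 4) stop("need at least 4 draws per chain")
  h <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(h), , drop = FALSE], x[h + seq_len(h), , drop = FALSE])
  w_vars <- apply(halves, 2, stats::var)
  W <- mean(w_vars)
  if (W == 0) {
    warning("zero within-chain variance in all chains; R-hat undefined")
    return(NaN)
  }
  B_over_n <- stats::var(colMeans(halves))
  var_plus <- (h - 1) / h * W + B_over_n
  sqrt(var_plus / W)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent draws, computed from the
#' combined-chain variance estimate and per-chain autocovariances with
#' Geyer's initial monotone positive-sequence truncation.
#'
#' @param chains Draws, as an iterations x chains matrix (single chains are
#'   accepted), or a list of equal-length numeric vectors.
#' @param max_lag Highest autocorrelation lag considered (default
#'   `min(n - 1, 1000)`).
#' @return The effective sample size; `NaN` with a warning for constant
#'   chains.
#' @export
effective_sample_size <- function(chains, max_lag = NULL) {
  x <- .as_chain_matrix(chains)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) stop("need at least 4 draws per chain")
  if (is.null(max_lag)) max_lag <- min(n - 1, 1000)
  acov <- vapply(seq_len(m), function(c) {
    stats::acf(x[, c], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1))
  acov <- matrix(acov, nrow = max_lag + 1)
  mean_acov <- rowMeans(acov)
  if (mean_acov[1] == 0) {
    warning("constant chains; effective sample size undefined")
    return(NaN)
  }
  W <- mean_acov[1] * n / (n - 1)
  B_over_n <- if (m > 1) stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence over lag pairs
  tau <- 0
  prev <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t + 1] + if (t + 2 <= length(rho)) rho[t + 2] else 0
    if (pair <= 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * tau)
  max(ess, .Machine$double.eps)
}

.as_chain_matrix <- function(chains) {
  if (is.list(chains) && !is.data.frame(chains)) {
    lens <- lengths(chains)
    if (length(unique(lens)) != 1) stop("chains must have equal length")
    chains <- do.call(cbind, lapply(chains, as.numeric))
  }
  x <- as.matrix(chains)
  storage.mode(x) <- "double"
  x
}
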