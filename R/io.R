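#' Read a hierarchical dataset from CSV
#'
#' Expects a header `product,batch,cycle,value` (RFC-4180, UTF-8, '.'
#' decimal separator). The `cycle` field may be empty for single-cycle rows;
#' row order is irrelevant. Per-product modes are inferred from the
#' structure and validated.
#'
#' @param path Path to a CSV file.
#' @return A [vm_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", na.strings = "")
  required <- c("product", "batch", "cycle", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) & !is.na(df$value))
  if (length(bad) > 0) {
    stop(path, ": non-numeric value(s) at line(s): ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  }
  df$value <- val
  tryCatch(vm_dataset(df), error = function(e) {
    stop(path, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Write a hierarchical dataset to CSV
#'
#' Inverse of [read_dataset()]; `NA` cycles are written as empty fields.
#' Values are printed with up to 15 significant digits, so a written file
#' read back and written again is byte-identical.
#'
#' @param data A [vm_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "vm_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Export posterior draws and diagnostics
#'
#' Writes the retained draws in long format (columns `chain`, `iteration`,
#' `parameter`, `value`) plus a JSON sidecar holding the per-parameter
#' diagnostics, sampler metadata and the resolved prior/MCMC configuration.
#'
#' @param fit A `vm_fit`.
#' @param draws_path Output CSV path.
#' @param diagnostics_path Optional output JSON path.
#' @return `draws_path`, invisibly.
#' @export
write_draws <- function(fit, draws_path, diagnostics_path = NULL) {
  a <- fit$draws
  d <- dim(a)
  long <- data.frame(
    chain = rep(seq_len(d[2]), each = d[1], times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(dimnames(a)[[3]], each = d[1] * d[2]),
    value = as.vector(a)
  )
  utils::write.csv(long, draws_path, row.names = FALSE, quote = TRUE)
  if (!is.null(diagnostics_path)) {
    jsonlite::write_json(
      list(
        diagnostics = fit$diagnostics,
        divergences = fit$divergences,
        treedepth_hits = fit$treedepth_hits,
        step_sizes = fit$step_sizes,
        accept_stats = fit$accept_stats,
        n_retained_draws = d[1] * d[2],
        prior = unclass(fit$prior),
        mcmc = unclass(fit$config)
      ),
      diagnostics_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(draws_path)
}

#' Import posterior draws written by [write_draws()]
#'
#' Rebuilds a minimal fit object (draw array plus diagnostics when the JSON
#' sidecar is given) sufficient for [extract_draws()],
#' [credible_interval()] and [posterior_predictive_S()].
#'
#' @param draws_path CSV path written by [write_draws()].
#' @param diagnostics_path Optional JSON sidecar path.
#' @return A `vm_fit`-like list.
#' @export
read_draws <- function(draws_path, diagnostics_path = NULL) {
  long <- utils::read.csv(draws_path, stringsAsFactors = FALSE)
  need <- c("chain", "iteration", "parameter", "value")
  if (!all(need %in% names(long))) {
    stop(draws_path, ": expected columns ", paste(need, collapse = ", "))
  }
  pars <- unique(long$parameter)
  chains <- sort(unique(long$chain))
  iters <- sort(unique(long$iteration))
  a <- array(
    NA_real_, dim = c(length(iters), length(chains), length(pars)),
    dimnames = list(NULL, paste0("chain", chains), pars)
  )
  idx <- cbind(
    match(long$iteration, iters), match(long$chain, chains),
    match(long$parameter, pars)
  )
  a[idx] <- long$value
  out <- list(draws = a)
  if (!is.null(diagnostics_path)) {
    out <- c(out, jsonlite::read_json(diagnostics_path, simplifyVector = TRUE))
  }
  structure(out, class = "vm_fit")
}

#' Lognormal QQ plausibility table
#'
#' Pairs the order statistics of `ln(sigma_hats)` with standard-normal
#' quantiles at plotting positions `(i - 0.5) / n`, scaled by a least-squares
#' fit of the ordered log values on the normal quantiles (the usual QQ-line
#' fit; for input lying exactly on lognormal quantiles the fit reproduces
#' the generating location and scale and the points fall on the identity
#' line). Points near the identity line support the lognormality of the
#' product-SD population, i.e. the pooling of these products in one
#' meta-analysis.
#'
#' @param sigma_hats At least 3 positive values: per-product posterior mean
#'   SDs, or plain sample SDs for a pre-fit plausibility check.
#' @return A data.frame with columns `theoretical` and `empirical`
#'   (log-SD scale), ready for plotting.
#' @export
qq_lognormal <- function(sigma_hats) {
  x <- as.numeric(sigma_hats)
  if (length(x) < 3) stop("need at least 3 values")
  if (any(!is.finite(x)) || any(x <= 0)) stop("all values must be positive")
  lx <- sort(log(x))
  if (stats::sd(lx) == 0) stop("degenerate input: zero variance on the log scale")
  n <- length(lx)
  z <- stats::qnorm((seq_len(n) - 0.5) / n)
  fit <- stats::lm.fit(cbind(1, z), lx)
  data.frame(
    theoretical = fit$coefficients[1] + fit$coefficients[2] * z,
    empirical = lx
  )
}

#' Per-product sample SDs of a dataset
#'
#' Simple plug-in estimates for the QQ plausibility check: the sample SD of
#' each single-cycle product's batch values, and for multi-cycle products
#' the square root of (between-batch variance of batch means + mean
#' within-batch variance).
#'
#' @param data A [vm_dataset()].
#' @return Named numeric vector of per-product SD estimates (`NA` where a
#'   product has fewer than 2 values).
#' @export
product_sample_sds <- function(data) {
  modes <- product_mode(data)
  vapply(names(modes), function(id) {
    pd <- product_data(data, id)
    if (modes[[id]] == "single_cycle") {
      if (length(pd) < 2) return(NA_real_)
      stats::sd(pd)
    } else {
      bm <- vapply(pd, mean, numeric(1))
      wv <- vapply(pd, function(v) {
        if (length(v) < 2) return(NA_real_)
        stats::var(v)
      }, numeric(1))
      sqrt(stats::var(bm) + mean(wv))
    }
  }, numeric(1))
}
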