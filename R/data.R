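#' Hierarchical measurement dataset
#'
#' Container for quality-attribute measurements organized product -> batch ->
#' cycle. Products whose batches each carry a single measurement are
#' *single-cycle*; products with at least one batch holding two or more cycle
#' measurements are *multi-cycle*. Both kinds can coexist in one dataset and
#' are integrated in a single meta-analysis fit.
#'
#' @param x A data.frame with columns `product`, `batch`, `value` and
#'   optionally `cycle` (may be `NA` for single-cycle rows). Labels are
#'   opaque strings; `value` must be finite numeric.
#' @param modes Optional named character vector (`"single_cycle"` /
#'   `"multi_cycle"` per product). If supplied it is cross-checked against the
#'   structure inferred from the data; a disagreement is an error.
#'
#' @return An object of class `vm_dataset`: the validated data.frame with a
#'   `modes` attribute mapping each product label to its mode.
#' @examples
#' d <- vm_dataset(data.frame(
#'   product = rep("A", 3), batch = c("b1", "b2", "b3"),
#'   cycle = NA, value = c(0.2, -0.1, 0.4)
#' ))
#' product_mode(d)
#' @export
vm_dataset <- function(x, modes = NULL) {
  if (!is.data.frame(x)) stop("`x` must be a data.frame")
  required <- c("product", "batch", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"cycle" %in% names(x)) x$cycle <- NA_character_
  x <- x[, c("product", "batch", "cycle", "value")]
  x$product <- as.character(x$product)
  x$batch <- as.character(x$batch)
  x$cycle <- as.character(x$cycle)
  if (nrow(x) == 0) stop("dataset has no measurements")
  if (!is.numeric(x$value)) stop("`value` must be numeric")
  bad <- which(!is.finite(x$value))
  if (length(bad) > 0) {
    stop("non-finite value(s) at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(x$product, x$batch, ifelse(is.na(x$cycle), "", x$cycle), sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(
      "duplicate (product, batch, cycle) key(s) at row(s): ",
      paste(utils::head(dup, 5), collapse = ", ")
    )
  }

  inferred <- .infer_modes(x)
  if (!is.null(modes)) {
    modes <- modes[names(inferred)]
    if (anyNA(modes)) stop("`modes` must name every product in the data")
    mism <- names(inferred)[modes != inferred]
    if (length(mism) > 0) {
      stop(
        "declared mode disagrees with data structure for product(s): ",
        paste(mism, collapse = ", ")
      )
    }
  }
  rownames(x) <- NULL
  structure(x, modes = inferred, class = c("vm_dataset", "data.frame"))
}

.infer_modes <- function(x) {
  products <- unique(x$product)
  vapply(products, function(p) {
    xi <- x[x$product == p, , drop = FALSE]
    per_batch <- table(xi$batch)
    if (any(per_batch >= 2)) "multi_cycle" else "single_cycle"
  }, character(1))
}

#' @rdname vm_dataset
#' @param data A `vm_dataset`.
#' @export
n_products <- function(data) length(attr(data, "modes"))

#' @rdname vm_dataset
#' @export
product_ids <- function(data) names(attr(data, "modes"))

#' @rdname vm_dataset
#' @export
product_mode <- function(data) attr(data, "modes")

#' Extract the measurements of one product
#'
#' @param data A `vm_dataset`.
#' @param id Product label.
#' @return For a single-cycle product, the numeric vector of batch values
#'   (named by batch). For a multi-cycle product, a named list of numeric
#'   vectors, one per batch, holding that batch's cycle values.
#' @export
product_data <- function(data, id) {
  modes <- attr(data, "modes")
  if (!id %in% names(modes)) stop("unknown product: ", id)
  xi <- data[data$product == id, , drop = FALSE]
  if (modes[[id]] == "single_cycle") {
    stats::setNames(xi$value, xi$batch)
  } else {
    split(xi$value, factor(xi$batch, levels = unique(xi$batch)))
  }
}

#' @export
print.vm_dataset <- function(x, ...) {
  modes <- attr(x, "modes")
  cat(
    "<vm_dataset> ", nrow(x), " measurements, ", length(modes), " products (",
    sum(modes == "single_cycle"), " single-cycle, ",
    sum(modes == "multi_cycle"), " multi-cycle)\n",
    sep = ""
  )
  print(as.data.frame(utils::head(x, 8)))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}
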