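#' Incomplete noisy 3-way observation tensor
#'
#' A 3-way value array together with a binary observation mask. Values at
#' masked-out positions are never read by the factorization; they are stored
#' as `NA`.
#'
#' @param values numeric 3-way array.
#' @param mask logical 3-way array of the same shape, `TRUE` for observed
#'   entries (default: non-`NA` values).
#' @param labels optional list of 3 character vectors labelling each mode.
#' @return An object of class `observed_tensor` with elements
#'   `values`, `mask`, `shape`, `labels`.
#' @export
observed_tensor <- function(values, mask = NULL, labels = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-way array")
  if (is.null(mask)) mask <- !is.na(values)
  if (!all(dim(mask) == dim(values)))
    stop("'mask' must have the same shape as 'values'")
  mask <- array(as.logical(mask), dim(values))
  if (anyNA(mask)) stop("'mask' entries must be TRUE/FALSE")
  if (any(!is.finite(values[mask])))
    stop("observed entries must be finite")
  values[!mask] <- NA_real_
  if (!is.null(labels)) {
    stopifnot(length(labels) == 3L,
              all(lengths(labels) == dim(values)))
  }
  structure(list(values = values, mask = mask, shape = dim(values),
                 labels = labels),
            class = "observed_tensor")
}

#' @export
print.observed_tensor <- function(x, ...) {
  cat(sprintf("observed_tensor: %s, %d/%d entries observed\n",
              paste(x$shape, collapse = " x "),
              sum(x$mask), length(x$mask)))
  invisible(x)
}
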