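# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.stopifnot_count <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

.stopifnot_fraction <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && hi_ok))
    stop(sprintf("'%s' must be in [0, %s)", name, if (allow_one) "1]" else "1"),
         call. = FALSE)
  invisible(as.numeric(x))
}
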