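# Internal helpers: seed derivation, validation, interval container.

# Deterministic child seed from a master seed and a stage offset.
# Kept strictly below 2^31 - 1 and computed so all intermediates stay
# exactly representable in doubles.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer(((seed %% 97651) * 21001 + offset * 7919 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be in [0, 1]")
  }
  invisible(x)
}

#' Interval estimate container
#'
#' A point estimate with a confidence interval, as produced by the
#' bootstrap and model-based estimators in this package.
#'
#' @param point,lower,upper numeric scalars, `lower <= point <= upper`.
#' @param level confidence level (default 0.95).
#' @param method character tag, e.g. `"stratified_bootstrap"`,
#'   `"bca_bootstrap"`, `"wald"`.
#' @return an object of class `interval_estimate`.
#' @export
interval_estimate <- function(point, lower, upper, level = 0.95, method = "unspecified") {
  stopifnot(is.numeric(point), is.numeric(lower), is.numeric(upper))
  if (!(lower <= point + 1e-12 && point <= upper + 1e-12)) {
    stop("interval_estimate requires lower <= point <= upper")
  }
  structure(
    list(point = point, lower = lower, upper = upper,
         level = level, method = method),
    class = "interval_estimate"
  )
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4g [%g%% CI: %.4g, %.4g] (%s)\n",
              x$point, 100 * x$level, x$lower, x$upper, x$method))
  invisible(x)
}
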