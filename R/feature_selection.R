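#' Balanced cross-validation fold assignment
#'
#' Randomly assigns `n` patients to `k` folds of as-equal-as-possible size
#' (sizes differ by at most one). The same assignment object is reused for
#' feature selection across all comparator model variants so that their
#' cross-validation folds are identical.
#'
#' @param n patient count.
#' @param k fold count (default 20).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return object of class `fold_assignment`: list with `fold` (fold id per
#'   patient), `k`, `seed`.
#' @export
assign_folds <- function(n, k = 20, seed = 1L) {
  if (k < 2 || k > n) stop("need 2 <= k <= n (got k = ", k, ", n = ", n, ")")
  fold <- withr::with_seed(derive_seed(seed, 11L),
                           sample(rep(seq_len(k), length.out = n)))
  structure(list(fold = fold, k = k, seed = seed), class = "fold_assignment")
}

#' Cross-validated LASSO feature selection
#'
#' Fits an L1-penalised (LASSO) linear model of the continuous outcome on
#' the design matrix with `glmnet`, choosing the penalty by minimum
#' cross-validated squared error over the supplied fold assignment.
#' Predictors are standardized internally; coefficients are reported on the
#' original scale. The selected set is the variables with non-zero
#' coefficients at the chosen penalty.
#'
#' A constant outcome (or a selection in which every coefficient is shrunk
#' to zero) yields an empty selection with a warning, not an error;
#' downstream model training falls back to an intercept-only comparator.
#'
#' @param X a `design_matrix` or numeric matrix.
#' @param y numeric outcome vector (the continuous 0/0.5/1 Gleason encoding
#'   in the study pipeline).
#' @param folds a [assign_folds()] result with `length(fold) == nrow(X)`.
#' @param standardize standardize predictors before penalisation (default
#'   TRUE; predictors mix ng/mL, years and log2 counts).
#' @return object of class `selected_features`: list with `variant`,
#'   `features`, `coefficients`, `lambda`, `fold_seed`.
#' @export
cv_lasso_select <- function(X, y, folds, standardize = TRUE) {
  variant <- if (inherits(X, "design_matrix")) X$variant else NA_character_
  x <- if (inherits(X, "design_matrix")) X$values else X
  stopifnot(is.matrix(x), is.numeric(y))
  if (nrow(x) != length(y)) stop("nrow(X) must equal length(y)")
  if (!inherits(folds, "fold_assignment") || length(folds$fold) != nrow(x)) {
    stop("folds must be a fold_assignment covering every patient")
  }
  empty <- structure(
    list(variant = variant, features = character(0),
         coefficients = numeric(0), lambda = NA_real_,
         fold_seed = folds$seed),
    class = "selected_features"
  )
  if (stats::var(y) == 0) {
    warning("constant outcome: no features selected")
    return(empty)
  }
  fit <- glmnet::cv.glmnet(x, y, family = "gaussian", alpha = 1,
                           foldid = folds$fold, standardize = standardize)
  beta <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
  nz <- beta != 0
  if (!any(nz)) {
    warning("LASSO shrank every coefficient to zero: empty selection")
    return(empty)
  }
  structure(
    list(variant = variant, features = names(beta)[nz],
         coefficients = beta[nz], lambda = fit$lambda.min,
         fold_seed = folds$seed),
    class = "selected_features"
  )
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features %s: %d feature(s), lambda = %.4g>\n",
              x$variant %||% "?", length(x$features), x$lambda))
  invisible(x)
}

#' Selection report across variants
#'
#' @param selections named list of `selected_features` (one per variant).
#' @param path optional JSON output path.
#' @return the report list, invisibly if written.
#' @export
selection_report <- function(selections, path = NULL) {
  rep <- lapply(selections, function(s) {
    list(features = s$features,
         coefficients = as.list(s$coefficients),
         lambda = s$lambda, fold_seed = s$fold_seed)
  })
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
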