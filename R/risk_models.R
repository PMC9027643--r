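#' Per-tree subsample index sets
#'
#' Draws the without-replacement subsample (size `ceiling(fraction * n)`)
#' used to grow each tree. Drawing these outside the forest fit lets the
#' exact same per-tree index sets be reused across all comparator model
#' variants, so their resamples are identical.
#'
#' @param n patient count.
#' @param n_trees number of trees (default 401).
#' @param fraction subsample fraction (default 0.632, the
#'   without-replacement convention of classical random-forest
#'   implementations).
#' @param seed integer seed.
#' @return list of `n_trees` integer index vectors.
#' @export
draw_subsamples <- function(n, n_trees = 401, fraction = 0.632, seed = 1L) {
  size <- ceiling(fraction * n)
  if (size >= n) stop("subsample fraction leaves no out-of-bag patients")
  if (size < 1) stop("subsample fraction too small")
  withr::with_seed(derive_seed(seed, 21L),
                   lapply(seq_len(n_trees), function(b) sort(sample.int(n, size))))
}

#' Train a regression random forest on the continuous Gleason encoding
#'
#' Grows a regression forest (401 trees by default, per-tree subsampling
#' without replacement, `mtry = floor(p/3)` and minimum node size 5, the
#' regression defaults of the classical implementation) on the design
#' matrix restricted to the LASSO-selected features. Deterministic given
#' `seed` and `subsamples`.
#'
#' @param X numeric predictor matrix (patients x selected features).
#' @param y continuous outcome in \[0, 1\].
#' @param n_trees number of trees (default 401).
#' @param sample_fraction per-tree subsample fraction (default 0.632).
#' @param min_node_size minimum terminal node size (default 5).
#' @param seed integer seed for tree growing.
#' @param subsamples optional pre-drawn index sets from [draw_subsamples()];
#'   drawn from `seed` if omitted.
#' @param variant optional model variant label.
#' @return object of class `forest_model`.
#' @export
train_forest <- function(X, y, n_trees = 401, sample_fraction = 0.632,
                         min_node_size = 5, seed = 1L, subsamples = NULL,
                         variant = NA_character_) {
  stopifnot(is.matrix(X), is.numeric(y), nrow(X) == length(y))
  if (ncol(X) == 0) {
    stop("empty feature set: fall back to an intercept-only comparator")
  }
  n <- nrow(X)
  if (is.null(subsamples)) {
    subsamples <- draw_subsamples(n, n_trees, sample_fraction, seed)
  }
  if (length(subsamples) != n_trees) stop("need one subsample index set per tree")
  inbag <- lapply(subsamples, function(idx) {
    if (length(idx) >= n) stop("per-tree in-sample set must be a strict subset")
    tabulate(idx, nbins = n)
  })
  df <- as.data.frame(X)
  fit <- ranger::ranger(
    x = df, y = y,
    num.trees = n_trees,
    mtry = max(1L, floor(ncol(X) / 3)),
    min.node.size = min_node_size,
    replace = FALSE,
    inbag = inbag,
    seed = derive_seed(seed, 22L),
    num.threads = 1
  )
  structure(
    list(fit = fit, inbag = do.call(cbind, inbag), X = df, y = y,
         n_trees = n_trees, variant = variant, seed = seed),
    class = "forest_model"
  )
}

#' Out-of-bag risk scores
#'
#' For each patient, averages the predictions of only those trees whose
#' in-sample subset excluded that patient. With 401 trees at subsample
#' fraction 0.632 every patient has out-of-bag trees with overwhelming
#' probability; an error is raised in the adversarial case where some
#' patient appears in every tree.
#'
#' @param model a [train_forest()] result.
#' @return object of class `risk_scores`: list with `variant`, `score`
#'   (named numeric in \[0, 1\]), `oob = TRUE`.
#' @export
oob_scores <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  oob <- model$inbag == 0
  n_oob <- rowSums(oob)
  if (any(n_oob == 0)) {
    stop("patient(s) with no out-of-bag tree: ",
         paste(which(n_oob == 0), collapse = ", "))
  }
  preds <- stats::predict(model$fit, data = model$X,
                          predict.all = TRUE, num.threads = 1)$predictions
  score <- rowSums(preds * oob) / n_oob
  names(score) <- rownames(model$X)
  risk_scores(model$variant, score, oob = TRUE)
}

risk_scores <- function(variant, score, oob) {
  structure(list(variant = variant, score = score, oob = oob),
            class = "risk_scores")
}

#' @export
print.risk_scores <- function(x, ...) {
  cat(sprintf("<risk_scores %s: n = %d, mean = %.3f%s>\n",
              x$variant %||% "?", length(x$score), mean(x$score),
              if (isTRUE(x$oob)) ", out-of-bag" else ""))
  invisible(x)
}

#' Build the four comparator models
#'
#' Runs the full modelling stage on a preprocessed-ready cohort: applies
#' the a-priori peptide filter and log2 transform, positive-control
#' normalisation of the EV-RNA counts, encodes the continuous outcome,
#' assigns one shared cross-validation fold set and one shared collection
#' of per-tree subsample index sets, then for each variant (SoC, MassSpec,
#' ExoRNA, ExoSpec) performs LASSO selection, trains the forest, and emits
#' out-of-bag risk scores. A variant whose selection comes back empty
#' proceeds as an intercept-only comparator (constant mean-outcome score)
#' with a warning.
#'
#' @param cohort a `cohort` from [generate_cohort()] or [read_cohort()].
#' @param k cross-validation fold count (default 20).
#' @param n_trees trees per forest (default 401).
#' @param sample_fraction per-tree subsample fraction (default 0.632).
#' @param seed master seed shared by fold assignment and subsampling.
#' @param min_frac peptide detection filter fraction (default 0.30).
#' @return object of class `comparator_set`: list with `scores` (named list
#'   of `risk_scores`), `selections`, `folds`, `y`, `strata`, `patients`.
#' @export
build_comparators <- function(cohort, k = 20, n_trees = 401,
                              sample_fraction = 0.632, seed = 1L,
                              min_frac = 0.30) {
  stopifnot(inherits(cohort, "cohort"))
  strata <- gleason_stratum(cohort$patients$stratum)
  y <- encode_outcome(strata)
  n <- length(y)

  pep <- log_transform_peptides(filter_peptides(cohort$peptide, strata, min_frac))
  rna <- normalize_evrna(cohort$evrna)
  clin <- cohort$clinical

  folds <- assign_folds(n, k = k, seed = seed)
  subs <- draw_subsamples(n, n_trees = n_trees, fraction = sample_fraction,
                          seed = seed)

  scores <- list(); selections <- list()
  for (v in model_variants()) {
    design <- assemble_design(clin, pep, rna, variant = v)
    sel <- cv_lasso_select(design, y, folds)
    selections[[v]] <- sel
    if (length(sel$features) == 0) {
      warning("variant ", v, ": empty selection, using intercept-only comparator")
      sc <- stats::setNames(rep(mean(y), n), cohort$patients$id)
      scores[[v]] <- risk_scores(v, sc, oob = FALSE)
      next
    }
    Xsel <- design$values[, sel$features, drop = FALSE]
    model <- train_forest(Xsel, y, n_trees = n_trees,
                          sample_fraction = sample_fraction,
                          seed = seed, subsamples = subs, variant = v)
    scores[[v]] <- oob_scores(model)
  }
  structure(
    list(scores = scores, selections = selections, folds = folds,
         y = y, strata = strata, patients = cohort$patients),
    class = "comparator_set"
  )
}

#' @export
print.comparator_set <- function(x, ...) {
  cat(sprintf("<comparator_set: %d patients, variants %s>\n",
              length(x$y), paste(names(x$scores), collapse = ", ")))
  invisible(x)
}
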