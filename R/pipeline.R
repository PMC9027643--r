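#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run: the synthetic cohort spec
#' (or a directory of cohort TSVs to load instead), cross-validation fold
#' count, forest size and subsample fraction, bootstrap resample counts,
#' the decision-threshold grid, target population prevalence, resample
#' size, and the master seed from which every stage derives its own seed.
#'
#' @param seed master seed (default 1).
#' @param spec a [synthetic_spec()]; ignored when `input_dir` is given.
#' @param input_dir optional directory of cohort TSVs ([read_cohort()]).
#' @param k cross-validation folds (default 20).
#' @param n_trees trees per forest (default 401).
#' @param sample_fraction per-tree subsample fraction (default 0.632).
#' @param B bootstrap resamples for AUC CIs, comparisons, mean differences
#'   and decision curves (default 1000).
#' @param thresholds decision threshold grid (default 0.05-0.50 by 0.01).
#' @param cap a [cap_prevalence()].
#' @param n_out prevalence-matched resample size (default 197).
#' @param outdir output directory (default a session temporary directory).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, spec = NULL, input_dir = NULL,
                       k = 20, n_trees = 401, sample_fraction = 0.632,
                       B = 1000, thresholds = seq(0.05, 0.50, by = 0.01),
                       cap = cap_prevalence(), n_out = 197,
                       outdir = file.path(tempdir(), "urisk_run")) {
  if (is.null(spec) && is.null(input_dir)) {
    spec <- synthetic_spec(seed = derive_seed(seed, 100L))
  }
  stopifnot(k >= 2, n_trees >= 1, B >= 2, n_out >= 1)
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("threshold grid must lie inside (0, 1)")
  }
  structure(
    list(seed = seed, spec = spec, input_dir = input_dir, k = k,
         n_trees = n_trees, sample_fraction = sample_fraction, B = B,
         thresholds = thresholds, cap = cap, n_out = n_out, outdir = outdir),
    class = "run_config"
  )
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1fs)", stage, paste(..., collapse = " "),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> select -> train ->
#' evaluate -> decision-curve analysis, writing every stage artifact and a
#' manifest into `config$outdir`: cohort TSVs, the selection report JSON,
#' an out-of-bag risk-score TSV, the evaluation report JSON, decision-curve
#' and biopsy-reduction TSVs, and `manifest.json` recording the config,
#' derived seeds, and an MD5 hash per output file. Identical config and
#' seed reproduce identical file hashes.
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly; the full results are attached as
#'   attribute `"results"`.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  t0 <- as.numeric(Sys.time())
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    generate_cohort(config$spec)
  }
  cohort_dir <- file.path(config$outdir, "cohort")
  files <- c(files, write_cohort(cohort, cohort_dir))
  stage_log("simulate", t0, nrow(cohort$patients), "patients;",
            ncol(cohort$peptide$values), "peptides;",
            ncol(cohort$evrna$values), "probes")

  t0 <- as.numeric(Sys.time())
  comparators <- build_comparators(
    cohort, k = config$k, n_trees = config$n_trees,
    sample_fraction = config$sample_fraction, seed = config$seed
  )
  sel_path <- file.path(config$outdir, "selection.json")
  selection_report(comparators$selections, sel_path)
  score_df <- do.call(rbind, lapply(names(comparators$scores), function(v) {
    data.frame(id = comparators$patients$id, variant = v,
               score = as_score_vector(comparators$scores[[v]]),
               stratum = as.character(comparators$strata))
  }))
  score_path <- file.path(config$outdir, "risk_scores.tsv")
  utils::write.table(score_df, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, sel_path, score_path)
  stage_log("select+train", t0, "4 variants,",
            paste(vapply(comparators$selections,
                         function(s) length(s$features), 0L), collapse = "/"),
            "features selected")

  t0 <- as.numeric(Sys.time())
  evaluation <- evaluate_models(comparators, B = config$B, seed = config$seed)
  eval_path <- file.path(config$outdir, "evaluation.json")
  eval_json <- list(
    auc = lapply(evaluation$auc, function(ep) lapply(ep, unclass)),
    comparisons = evaluation$comparisons,
    odds_ratio = unclass(evaluation$odds_ratio),
    mean_differences = lapply(evaluation$mean_differences, unclass)
  )
  jsonlite::write_json(eval_json, eval_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, eval_path)
  stage_log("evaluate", t0, length(evaluation$auc), "endpoints x",
            length(comparators$scores), "variants")

  t0 <- as.numeric(Sys.time())
  curves <- list(); reductions <- list()
  for (ep in endpoint_names()) {
    cur <- decision_curves(
      comparators$scores, comparators$strata, cohort$patients$psa,
      endpoint = ep, thresholds = config$thresholds, cap = config$cap,
      n_out = config$n_out, B = config$B, seed = config$seed
    )
    curves[[ep]] <- cur
    reductions[[ep]] <- biopsy_reduction_table(cur)
  }
  dca_path <- file.path(config$outdir, "decision_curves.tsv")
  red_path <- file.path(config$outdir, "biopsy_reduction.tsv")
  utils::write.table(do.call(rbind, lapply(curves, as.data.frame)),
                     dca_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, reductions),
                     red_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, dca_path, red_path)
  stage_log("dca", t0, length(curves), "endpoints x",
            length(config$thresholds), "thresholds")

  manifest <- list(
    seed = config$seed,
    k = config$k, n_trees = config$n_trees,
    sample_fraction = config$sample_fraction, B = config$B,
    n_out = config$n_out, cap = unclass(config$cap),
    thresholds = config$thresholds,
    stage_seeds = list(folds = derive_seed(config$seed, 11L),
                       subsamples = derive_seed(config$seed, 21L)),
    files = as.list(tools::md5sum(unname(files)))
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  results <- list(cohort = cohort, comparators = comparators,
                  evaluation = evaluation, curves = curves,
                  reductions = reductions)
  invisible(structure(manifest, results = results))
}
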