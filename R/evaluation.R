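as_score_vector <- function(scores) {
  if (inherits(scores, "risk_scores")) scores$score else as.numeric(scores)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the chance a random positive
#' outscores a random negative, with ties counted one half (computed from
#' midranks).
#'
#' @param scores numeric vector or `risk_scores`.
#' @param labels logical endpoint labels (TRUE = positive).
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  s <- as_score_vector(scores)
  labels <- as.logical(labels)
  stopifnot(length(s) == length(labels), !anyNA(s), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present to compute AUC")
  r <- rank(s)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Draw B stratified resamples (positives and negatives resampled
# separately, with replacement) and return the statistic applied to each.
stratified_boot <- function(labels, B, seed, stat) {
  pos <- which(labels); neg <- which(!labels)
  withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      stat(idx)
    }, numeric(1))
  })
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples positives and negatives separately with replacement and
#' reports the percentile interval of the resampled AUCs.
#'
#' @inheritParams roc_auc
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return an [interval_estimate()] with method `"stratified_bootstrap"`.
#' @export
auc_ci <- function(scores, labels, B = 1000, seed = 1L, level = 0.95) {
  if (B < 2) stop("B must be >= 2")
  s <- as_score_vector(scores)
  labels <- as.logical(labels)
  point <- roc_auc(s, labels)
  aucs <- stratified_boot(labels, B, derive_seed(seed, 31L),
                          function(idx) roc_auc(s[idx], labels[idx]))
  q <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  interval_estimate(point, min(q[1], point), max(q[2], point),
                    level = level, method = "stratified_bootstrap")
}

#' Paired bootstrap comparison of two models' AUCs
#'
#' One-sided test that model `a` discriminates better than model `b` on the
#' same patients: both models are evaluated on identical stratified
#' resamples and the p-value is the add-one-corrected proportion of
#' resamples with `AUC(a) - AUC(b) <= 0`, so p is never exactly 0.
#'
#' @param scores_a,scores_b paired score vectors (or `risk_scores`) on the
#'   same patients.
#' @inheritParams auc_ci
#' @return one-sided p-value in (0, 1\].
#' @export
auc_diff_pvalue <- function(scores_a, scores_b, labels, B = 1000, seed = 1L) {
  a <- as_score_vector(scores_a); b <- as_score_vector(scores_b)
  if (length(a) != length(b)) stop("paired scores must have equal length")
  labels <- as.logical(labels)
  stopifnot(length(a) == length(labels))
  delta <- stratified_boot(labels, B, derive_seed(seed, 32L), function(idx) {
    roc_auc(a[idx], labels[idx]) - roc_auc(b[idx], labels[idx])
  })
  (1 + sum(delta <= 0)) / (B + 1)
}

#' Proportional-odds association of the risk score with the ordinal outcome
#'
#' Fits a cumulative-logit proportional-odds model of the ordinal biopsy
#' category (No Cancer < Gleason 3+3 < 3+4 < 4+3 < >= 4+4; the two
#' no-cancer subtypes are merged) on the risk score, and reports the odds
#' ratio per `unit` score increase with a Wald 95% confidence interval.
#'
#' @param scores numeric vector or `risk_scores`.
#' @param strata per-patient stratum vector.
#' @param unit score increment the odds ratio refers to (default 0.1).
#' @param level confidence level (default 0.95).
#' @return an [interval_estimate()] of the odds ratio, method `"wald"`.
#' @export
prop_odds_or <- function(scores, strata, unit = 0.1, level = 0.95) {
  s <- as_score_vector(scores)
  st <- gleason_stratum(strata)
  ord_lab <- ifelse(is_cancer(st), as.character(st), "NC")
  ord <- factor(ord_lab, levels = c("NC", "GS3_3", "GS3_4", "GS4_3", "GS4PLUS"),
                ordered = TRUE)
  ord <- droplevels(ord)
  if (nlevels(ord) < 3) stop("need at least 3 ordinal outcome levels present")
  df <- data.frame(ord = ord, score = s)
  fit <- tryCatch(
    MASS::polr(ord ~ score, data = df, Hess = TRUE),
    error = function(e) stop("proportional-odds model failed to converge: ",
                             conditionMessage(e))
  )
  beta <- stats::coef(fit)[["score"]]
  se <- sqrt(stats::vcov(fit)["score", "score"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  interval_estimate(exp(unit * beta), exp(unit * (beta - z * se)),
                    exp(unit * (beta + z * se)),
                    level = level, method = "wald")
}

#' BCa bootstrap interval for a two-group mean difference
#'
#' Estimation-statistics style mean difference `mean(group_b) -
#' mean(group_a)` with a bias-corrected and accelerated (BCa) bootstrap
#' confidence interval: both groups are resampled with replacement, the
#' bias correction comes from the proportion of bootstrap estimates below
#' the point estimate, and the acceleration from the jackknife skewness.
#'
#' @param group_a,group_b numeric vectors (e.g. risk scores of two clinical
#'   groups), each of size >= 2.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return an [interval_estimate()] with method `"bca_bootstrap"`.
#' @export
bca_mean_diff <- function(group_a, group_b, B = 1000, seed = 1L, level = 0.95) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2) stop("both groups need size >= 2")
  point <- mean(b) - mean(a)
  boots <- withr::with_seed(derive_seed(seed, 33L), {
    vapply(seq_len(B), function(i) {
      mean(sample(b, replace = TRUE)) - mean(sample(a, replace = TRUE))
    }, numeric(1))
  })
  if (length(unique(boots)) == 1) {
    return(interval_estimate(point, boots[1], boots[1],
                             level = level, method = "bca_bootstrap"))
  }
  # bias correction
  z0 <- stats::qnorm(pmin(pmax(mean(boots < point), 1 / (B + 1)), B / (B + 1)))
  # acceleration from jackknife over all observations of both groups
  jack <- c(
    vapply(seq_along(a), function(i) mean(b) - mean(a[-i]), numeric(1)),
    vapply(seq_along(b), function(i) mean(b[-i]) - mean(a), numeric(1))
  )
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  accel <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)
  zalpha <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - accel * (z0 + zalpha)))
  q <- stats::quantile(boots, adj, names = FALSE)
  interval_estimate(point, min(q[1], point), max(q[2], point),
                    level = level, method = "bca_bootstrap")
}

#' Evaluation report across variants and endpoints
#'
#' Computes, for every model variant and endpoint, the AUC with stratified
#' bootstrap CI, plus one-sided paired bootstrap p-values of ExoSpec
#' against each single-block model, the proportional-odds odds ratio of
#' the ExoSpec score, and BCa mean differences of the ExoSpec score
#' between NEC and every other clinical group.
#'
#' @param comparators a [build_comparators()] result.
#' @param B bootstrap resample count (default 1000).
#' @param seed integer seed.
#' @return a list report (auc, comparisons, odds_ratio, mean_differences).
#' @export
evaluate_models <- function(comparators, B = 1000, seed = 1L) {
  stopifnot(inherits(comparators, "comparator_set"))
  strata <- comparators$strata
  scores <- comparators$scores
  auc <- list(); comparisons <- list()
  for (ep in endpoint_names()) {
    labels <- endpoint_labels(strata, ep)
    auc[[ep]] <- lapply(scores, function(sc) auc_ci(sc, labels, B = B, seed = seed))
    comparisons[[ep]] <- lapply(
      scores[setdiff(names(scores), "ExoSpec")],
      function(sc) auc_diff_pvalue(scores$ExoSpec, sc, labels, B = B, seed = seed)
    )
  }
  exo <- as_score_vector(scores$ExoSpec)
  or <- prop_odds_or(exo, strata)
  # estimation-plot grouping: NEC, raised-PSA negative biopsy, Gs3+3,
  # Gs3+4, Gs>=4+3 (high-grade strata merged)
  groups <- ifelse(ge_4_3(strata), "GS4_3PLUS", as.character(strata))
  nec <- exo[groups == "NEC"]
  mean_diffs <- list()
  for (g in setdiff(unique(groups), "NEC")) {
    if (sum(groups == g) >= 2 && length(nec) >= 2) {
      mean_diffs[[g]] <- bca_mean_diff(nec, exo[groups == g], B = B, seed = seed)
    }
  }
  list(auc = auc, comparisons = comparisons, odds_ratio = or,
       mean_differences = mean_diffs)
}
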