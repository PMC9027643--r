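#' Target population Gleason prevalence for decision-curve resampling
#'
#' Biopsy-outcome proportions observed in the control arm of a large
#' population PSA-screening trial, used as the target population for
#' prevalence-matched resampling: 60.6% no evidence of cancer, 23.6%
#' Gleason 6, 8.7% Gleason 7, 7.1% Gleason >= 8.
#'
#' @param nc,gs6,gs7,gs8plus stratum proportions; must sum to 1.
#' @return object of class `cap_prevalence`.
#' @export
cap_prevalence <- function(nc = 0.606, gs6 = 0.236, gs7 = 0.087, gs8plus = 0.071) {
  p <- c(NC = nc, GS6 = gs6, GS7 = gs7, GS8PLUS = gs8plus)
  assert_prob(p, "prevalence proportions")
  if (abs(sum(p) - 1) > 1e-9) stop("prevalence proportions must sum to 1")
  structure(as.list(p), class = "cap_prevalence")
}

# map the six cohort strata onto the trial's reported Gleason-sum groups
cap_group <- function(strata) {
  s <- gleason_stratum(strata)
  out <- character(length(s))
  out[as.character(s) %in% c("NEC", "NEG_BIOPSY")] <- "NC"
  out[as.character(s) == "GS3_3"] <- "GS6"
  out[as.character(s) %in% c("GS3_4", "GS4_3")] <- "GS7"
  out[as.character(s) == "GS4PLUS"] <- "GS8PLUS"
  out
}

# largest-remainder apportionment of n among proportions p (ties broken in
# the order of p)
largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    up <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[up] <- counts[up] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Prevalence-matched stratified resample
#'
#' Draws a bootstrap resample of fixed size whose stratum composition
#' exactly matches the target population prevalence (largest-remainder
#' rounding of proportion x `n_out`), sampling uniformly with replacement
#' within each stratum. With the default proportions and `n_out = 197` the
#' stratum counts are 119 NC, 47 GS6, 17 GS7, 14 GS >= 8 in every draw.
#'
#' @param strata per-patient stratum vector.
#' @param cap a [cap_prevalence()].
#' @param n_out resample size (default 197).
#' @param seed integer seed.
#' @return integer vector of `n_out` patient indices (a multiset).
#' @export
cap_resample <- function(strata, cap = cap_prevalence(), n_out = 197, seed = 1L) {
  stopifnot(inherits(cap, "cap_prevalence"))
  grp <- cap_group(strata)
  p <- unlist(cap)
  targets <- largest_remainder(p, n_out)
  withr::with_seed(seed, {
    idx <- integer(0)
    for (g in names(targets)) {
      if (targets[g] == 0) next
      pool <- which(grp == g)
      if (length(pool) == 0) {
        stop("cohort has no patients in required stratum ", g)
      }
      idx <- c(idx, pool[sample.int(length(pool), targets[g], replace = TRUE)])
    }
    idx
  })
}

#' Net benefit of a biopsy decision rule
#'
#' Patients with `score >= t` are biopsied. Net benefit weighs true
#' positives against false positives at the odds implied by the accepted
#' risk threshold: `NB = TP/n - (FP/n) * t/(1-t)`.
#'
#' @param scores numeric vector or `risk_scores`.
#' @param labels logical endpoint labels.
#' @param t decision threshold in (0, 1).
#' @return list with `nb`, `tp`, `fp`.
#' @export
net_benefit <- function(scores, labels, t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t >= 1) {
    stop("threshold t must lie strictly inside (0, 1)")
  }
  s <- as_score_vector(scores)
  labels <- as.logical(labels)
  stopifnot(length(s) == length(labels))
  sel <- s >= t
  tp <- sum(sel & labels); fp <- sum(sel & !labels)
  n <- length(s)
  list(nb = tp / n - (fp / n) * t / (1 - t), tp = tp, fp = fp)
}

#' Standardized net benefit
#'
#' Net benefit divided by endpoint prevalence, so a perfect rule scores 1
#' and treat-none scores 0.
#'
#' @param nb net benefit value.
#' @param prevalence endpoint prevalence, > 0.
#' @return sNB value.
#' @export
snb <- function(nb, prevalence) {
  if (any(prevalence <= 0)) stop("prevalence must be > 0")
  nb / prevalence
}

#' Net benefit of the treat-all policy
#'
#' The clinical default policy: biopsy every man with PSA >= 4 ng/mL,
#' regardless of the decision threshold (the threshold still sets the
#' false-positive weight in the net-benefit formula).
#'
#' @param psa per-patient PSA (ng/mL).
#' @param labels logical endpoint labels.
#' @param t decision threshold in (0, 1).
#' @param psa_cutoff biopsy-triggering PSA (default 4).
#' @return list with `nb`, `tp`, `fp`.
#' @export
treat_all_nb <- function(psa, labels, t, psa_cutoff = 4) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t >= 1) {
    stop("threshold t must lie strictly inside (0, 1)")
  }
  labels <- as.logical(labels)
  stopifnot(length(psa) == length(labels))
  sel <- psa >= psa_cutoff
  tp <- sum(sel & labels); fp <- sum(sel & !labels)
  n <- length(psa)
  list(nb = tp / n - (fp / n) * t / (1 - t), tp = tp, fp = fp)
}

# vectorized over thresholds: NB(t) for biopsy-iff-score>=t
nb_over_thresholds <- function(scores, labels, thresholds) {
  ge <- outer(thresholds, scores, "<=")  # B(t) x n selection matrix
  tp <- as.numeric(ge %*% labels)
  fp <- as.numeric(ge %*% (!labels))
  n <- length(scores)
  tp / n - (fp / n) * thresholds / (1 - thresholds)
}

#' Decision curves under prevalence-matched resampling
#'
#' For each of `B` prevalence-matched stratified resamples, computes the
#' standardized net benefit of every model, the treat-all (PSA >= 4)
#' policy, and treat-none at every threshold, standardizing by the
#' endpoint prevalence within that resample, and reports the mean across
#' resamples. Mean (unstandardized) net benefit is retained alongside for
#' the biopsy net-reduction metric.
#'
#' @param scores_list named list of score vectors / `risk_scores`
#'   (row-aligned with `strata`).
#' @param strata per-patient stratum vector.
#' @param psa per-patient PSA for the treat-all policy.
#' @param endpoint endpoint name, see [endpoint_labels()].
#' @param thresholds strictly increasing grid inside (0, 1); default
#'   0.05-0.50 by 0.01.
#' @param cap a [cap_prevalence()].
#' @param n_out resample size (default 197).
#' @param B number of resamples (default 1000).
#' @param seed integer seed.
#' @return object of class `decision_curve`: data.frame with columns
#'   `endpoint`, `threshold`, `model`, `snb`, `nb` (models plus
#'   `treat_all` and `treat_none`), with attributes `B`, `n_out`, `seed`.
#' @export
decision_curves <- function(scores_list, strata, psa,
                            endpoint = c("any_cancer", "ge_3_4", "ge_4_3"),
                            thresholds = seq(0.05, 0.50, by = 0.01),
                            cap = cap_prevalence(), n_out = 197,
                            B = 1000, seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must be strictly increasing within (0, 1)")
  }
  s_mat <- lapply(scores_list, as_score_vector)
  n <- length(gleason_stratum(strata))
  stopifnot(all(vapply(s_mat, length, 0L) == n), length(psa) == n)
  labels_all <- endpoint_labels(strata, endpoint)
  models <- names(s_mat)
  acc_snb <- matrix(0, length(thresholds), length(models) + 1,
                    dimnames = list(NULL, c(models, "treat_all")))
  acc_nb <- acc_snb
  for (b in seq_len(B)) {
    idx <- cap_resample(strata, cap, n_out, seed = derive_seed(seed, 41L + b))
    lab <- labels_all[idx]
    prev <- mean(lab)
    for (m in models) {
      nb <- nb_over_thresholds(s_mat[[m]][idx], lab, thresholds)
      acc_nb[, m] <- acc_nb[, m] + nb
      acc_snb[, m] <- acc_snb[, m] + nb / prev
    }
    sel <- psa[idx] >= 4
    tp <- sum(sel & lab); fp <- sum(sel & !lab)
    nb_ta <- tp / n_out - (fp / n_out) * thresholds / (1 - thresholds)
    acc_nb[, "treat_all"] <- acc_nb[, "treat_all"] + nb_ta
    acc_snb[, "treat_all"] <- acc_snb[, "treat_all"] + nb_ta / prev
  }
  acc_nb <- acc_nb / B; acc_snb <- acc_snb / B
  out <- do.call(rbind, lapply(colnames(acc_snb), function(m) {
    data.frame(endpoint = endpoint, threshold = thresholds, model = m,
               snb = acc_snb[, m], nb = acc_nb[, m])
  }))
  out <- rbind(out, data.frame(endpoint = endpoint, threshold = thresholds,
                               model = "treat_none", snb = 0, nb = 0))
  rownames(out) <- NULL
  structure(out, class = c("decision_curve", "data.frame"),
            B = B, n_out = n_out, seed = seed)
}

#' Net reduction in biopsies relative to standard of care
#'
#' `(nb_model - nb_soc) * (1 - t)/t`, reported per 100 patients: the number
#' of unnecessary biopsies avoided per 100 men at accepted risk threshold
#' `t`, relative to the clinical standard-of-care model, without missing
#' any additional true positives.
#'
#' @param nb_model,nb_soc net benefit of the candidate and the
#'   standard-of-care model at threshold `t` (vectors allowed).
#' @param t decision threshold(s) in (0, 1).
#' @return biopsy reduction per 100 patients.
#' @examples
#' biopsy_net_reduction(0.175, 0.125, 0.25)  # 15 per 100 patients
#' @export
biopsy_net_reduction <- function(nb_model, nb_soc, t) {
  if (any(t <= 0) || any(t >= 1)) stop("threshold t must lie strictly inside (0, 1)")
  (nb_model - nb_soc) * (1 - t) / t * 100
}

#' Biopsy-reduction table from a decision curve
#'
#' Applies [biopsy_net_reduction()] to the mean net benefit of every model
#' in a [decision_curves()] result, relative to the SoC model.
#'
#' @param curve a `decision_curve`.
#' @param reference model name used as standard of care (default "SoC").
#' @return data.frame with columns `endpoint`, `threshold`, `model`,
#'   `reduction_per_100`.
#' @export
biopsy_reduction_table <- function(curve, reference = "SoC") {
  stopifnot(inherits(curve, "decision_curve"))
  soc <- curve[curve$model == reference, ]
  if (nrow(soc) == 0) stop("reference model '", reference, "' not in curve")
  others <- setdiff(unique(curve$model), c(reference, "treat_none"))
  do.call(rbind, lapply(others, function(m) {
    cm <- curve[curve$model == m, ]
    stopifnot(identical(cm$threshold, soc$threshold))
    data.frame(endpoint = cm$endpoint, threshold = cm$threshold, model = m,
               reduction_per_100 = biopsy_net_reduction(cm$nb, soc$nb, cm$threshold))
  }))
}
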