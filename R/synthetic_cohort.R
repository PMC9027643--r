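#' Default planted-effect table
#'
#' Linear fold changes (all prostate cancer vs no-cancer, on the detected-value
#' scale) for the informative features planted by the synthetic generator:
#' 14 urinary peptides and 6 EV-RNA probes. Fold changes below 1 mark
#' features depleted in cancer. Feature names echo the proteins/genes the
#' corresponding markers derive from; they are synthetic stand-ins, not
#' measured data.
#'
#' @return data.frame with columns `feature`, `block`, `fold`.
#' @export
default_effect_table <- function() {
  rbind(
    data.frame(
      feature = c("PEP_HIST1H1E", "PEP_COL2A1", "PEP_COL1A1_a", "PEP_FGA_a",
                  "PEP_COL4A4", "PEP_MMP2", "PEP_FGA_b", "PEP_FGA_c",
                  "PEP_NADK", "PEP_COL1A1_b", "PEP_COL1A1_c", "PEP_COL4A3",
                  "PEP_COL4A5", "PEP_GLUD1"),
      block = "peptide",
      fold = c(7.1, 7.0, 6.4, 5.6, 5.4, 4.8, 4.1, 3.2, 1.3, 0.7, 0.6, 0.6, 0.6, 0.5)
    ),
    data.frame(
      feature = c("ERG", "PCA3", "SLC12A1", "TMEM45B", "SERPINB5", "SNORA20"),
      block = "evrna",
      fold = c(4.8, 4.2, 3.5, 1.9, 0.8, 0.8)
    )
  )
}

default_group_sizes <- function() {
  c(NEC = 23, NEG_BIOPSY = 36, GS3_3 = 31, GS3_4 = 48, GS4_3 = 25, GS4PLUS = 29)
}

# Stratum-specific clinical distributions, calibrated to the development
# cohort summaries: no-cancer PSA median ~5.3 ng/mL (mixture of low-PSA
# unbiopsied men and raised-PSA biopsy-negative men), cancer median ~10.4;
# no-cancer age mean 66.2 (sd 8.3), cancer mean ~70.2 (sd 7.8), with a mild
# gradient over Gleason strata so the continuous outcome is learnable.
default_clinical_params <- function() {
  list(
    age_mean = c(NEC = 66.2, NEG_BIOPSY = 66.2, GS3_3 = 69, GS3_4 = 70,
                 GS4_3 = 71, GS4PLUS = 72),
    age_sd = c(NEC = 8.3, NEG_BIOPSY = 8.3, GS3_3 = 7.8, GS3_4 = 7.8,
               GS4_3 = 7.8, GS4PLUS = 7.8),
    psa_meanlog = log(c(NEC = 2.5, NEG_BIOPSY = 6.5, GS3_3 = 9.5, GS3_4 = 10.4,
                        GS4_3 = 11.5, GS4PLUS = 12.5)),
    psa_sdlog = c(NEC = 0.5, NEG_BIOPSY = 0.35, GS3_3 = 0.55, GS3_4 = 0.55,
                  GS4_3 = 0.55, GS4PLUS = 0.55),
    # DRE prostate-size impression frequencies (Small/Medium/Large/Unknown):
    # cohort-pooled marginals, identical in both groups, so DRE carries no
    # outcome signal and the clinical block's informative variables are age
    # and PSA only (mirroring the reported clinical selection)
    dre_probs_nc = c(Small = 0.146, Medium = 0.479, Large = 0.271, Unknown = 0.104),
    dre_probs_pca = c(Small = 0.146, Medium = 0.479, Large = 0.271, Unknown = 0.104),
    urine_meanlog = log(35), urine_sdlog = 0.45,
    cancer_shift = TRUE
  )
}

#' Synthetic cohort specification
#'
#' Defines the generative model for a synthetic development cohort: group
#' sizes per Gleason stratum, planted feature effects (linear fold changes,
#' all-cancer vs no-cancer), block dimensions, the peptide detection model,
#' log-scale noise, and stratum-specific clinical distributions.
#'
#' Defaults reproduce the structure of the 192-patient development cohort:
#' 59 no-cancer patients (23 no-evidence-of-cancer, 36 biopsy-negative),
#' 31 Gleason 3+3, 48 Gleason 3+4, 25 Gleason 4+3, 29 Gleason >= 4+4;
#' 643 peptides, 167 EV-RNA probes (plus 6 synthetic positive-control
#' probes), and the default planted-effect table.
#'
#' @param group_sizes named integer vector over [gleason_levels()].
#' @param effect_table data.frame(feature, block, fold); fold changes > 0.
#' @param n_peptides,n_evrna feature counts for the two omics blocks.
#' @param peptide_detection_rate baseline probability that a peptide is
#'   detected (non-zero) in a sample.
#' @param noise_sd log-scale noise standard deviation (natural log for
#'   peptide intensities, log2 for EV-RNA counts).
#' @param clinical_params list of stratum-specific clinical distribution
#'   parameters; see `default_clinical_params()` source for fields.
#' @param seed integer master seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(group_sizes = default_group_sizes(),
                           effect_table = default_effect_table(),
                           n_peptides = 643,
                           n_evrna = 167,
                           peptide_detection_rate = 0.7,
                           noise_sd = 1.5,
                           clinical_params = default_clinical_params(),
                           seed = 1L) {
  spec <- structure(
    list(group_sizes = group_sizes, effect_table = effect_table,
         n_peptides = n_peptides, n_evrna = n_evrna,
         peptide_detection_rate = peptide_detection_rate,
         noise_sd = noise_sd, clinical_params = clinical_params,
         seed = seed),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  gs <- spec$group_sizes
  if (is.null(names(gs)) || !setequal(names(gs), gleason_levels())) {
    stop("group_sizes must be named over all six Gleason strata")
  }
  if (any(gs < 0) || any(gs != round(gs))) {
    stop("group_sizes must be non-negative integers")
  }
  n_nc <- sum(gs[c("NEC", "NEG_BIOPSY")])
  n_ca <- sum(gs[c("GS3_3", "GS3_4", "GS4_3", "GS4PLUS")])
  if (sum(gs) < 2 || n_nc < 1 || n_ca < 1) {
    stop("group_sizes must include at least one no-cancer and one cancer patient")
  }
  et <- spec$effect_table
  if (nrow(et) > 0) {
    if (!all(c("feature", "block", "fold") %in% names(et))) {
      stop("effect_table must have columns feature, block, fold")
    }
    if (any(!et$block %in% c("peptide", "evrna"))) {
      stop("effect_table block must be 'peptide' or 'evrna'")
    }
    if (any(!is.finite(et$fold)) || any(et$fold <= 0)) {
      stop("effect_table fold changes must be positive")
    }
    if (anyDuplicated(paste(et$block, et$feature))) {
      stop("effect_table has duplicated features")
    }
    if (sum(et$block == "peptide") > spec$n_peptides) {
      stop("n_peptides smaller than the number of peptide effect_table entries")
    }
    if (sum(et$block == "evrna") > spec$n_evrna) {
      stop("n_evrna smaller than the number of evrna effect_table entries")
    }
  }
  if (spec$n_peptides < 0 || spec$n_evrna < 0) stop("n_peptides/n_evrna must be >= 0")
  assert_prob(spec$peptide_detection_rate, "peptide_detection_rate")
  if (spec$peptide_detection_rate <= 0) stop("peptide_detection_rate must be > 0")
  if (!is.numeric(spec$noise_sd) || spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.numeric(spec$seed) || length(spec$seed) != 1) stop("seed must be a single integer")
  invisible(spec)
}

# Per-stratum fold multipliers for one planted feature. The quoted fold
# change is the all-cancer vs no-cancer contrast on the detected-value
# scale; within cancer the effect scales with stratum ordinality
# (GS3_3 < GS3_4 < GS4_3 < GS4PLUS) so the continuous outcome encoding is
# learnable. Linear construction keeps the size-weighted mean multiplier
# exactly equal to the quoted fold.
stratum_folds <- function(fold, group_sizes) {
  w <- c(GS3_3 = 0.5, GS3_4 = 0.75, GS4_3 = 1.25, GS4PLUS = 1.5)
  n <- group_sizes[names(w)]
  active <- n > 0
  cc <- sum(n[active]) / sum(n[active] * w[active])
  f <- 1 + cc * w * (fold - 1)
  f[!active] <- 1
  if (any(f[active] <= 0)) {
    stop("fold change ", fold, " too extreme for the stratum effect gradient")
  }
  c(NEC = 1, NEG_BIOPSY = 1, f)
}

#' Generate a synthetic development cohort
#'
#' Draws a full synthetic cohort from a [synthetic_spec()]: a patient table
#' (id, age, PSA, DRE size, urine volume, stratum), a clinical block, a raw
#' CE-MS-like peptide intensity block (exact zeros = not detected; detected
#' intensities log-normal with cancer-stratum mean shifts for planted
#' features), and a raw EV-RNA count block (log2-normal, with six synthetic
#' positive-control probes carrying a per-sample lane factor that also
#' multiplies the endogenous probes, so positive-control normalisation is
#' meaningful).
#'
#' Deterministic given `spec$seed`; each block uses a child generator
#' derived from the master seed by a fixed offset.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `cohort`: list with `patients` (data.frame),
#'   `clinical`, `peptide`, `evrna` ([omics_block]s), and `spec`.
#' @examples
#' coh <- generate_cohort(synthetic_spec(seed = 7))
#' nrow(coh$patients)  # 192
#' @export
generate_cohort <- function(spec) {
  validate_synthetic_spec(spec)
  gs <- spec$group_sizes[gleason_levels()]
  n <- sum(gs)
  stratum <- gleason_stratum(rep(gleason_levels(), times = gs))
  ids <- sprintf("P%04d", seq_len(n))

  cp <- spec$clinical_params
  patients <- withr::with_seed(derive_seed(spec$seed, 1L), {
    s <- as.character(stratum)
    age <- pmax(40, stats::rnorm(n, cp$age_mean[s], cp$age_sd[s]))
    psa <- stats::rlnorm(n, cp$psa_meanlog[s], cp$psa_sdlog[s])
    dre <- character(n)
    nc <- !is_cancer(stratum)
    dre[nc] <- sample(names(cp$dre_probs_nc), sum(nc), replace = TRUE,
                      prob = cp$dre_probs_nc)
    dre[!nc] <- sample(names(cp$dre_probs_pca), sum(!nc), replace = TRUE,
                       prob = cp$dre_probs_pca)
    urine <- stats::rlnorm(n, cp$urine_meanlog, cp$urine_sdlog)
    data.frame(
      id = ids, age = round(age, 1), psa = round(psa, 2),
      dre_size = dre, urine_volume = round(urine, 1),
      stratum = s,
      nc_subtype = ifelse(nc, s, NA_character_),
      stringsAsFactors = FALSE
    )
  })

  et <- spec$effect_table
  peptide <- withr::with_seed(derive_seed(spec$seed, 2L), {
    gen_block(n, spec$n_peptides, stratum, gs,
              effects = et[et$block == "peptide", , drop = FALSE],
              prefix = "PEP", base_log = stats::rnorm(spec$n_peptides, log(500), 1),
              log_base = exp(1), noise_sd = spec$noise_sd,
              detection_rate = spec$peptide_detection_rate)
  })
  rownames(peptide) <- ids

  evrna <- withr::with_seed(derive_seed(spec$seed, 3L), {
    base_log2 <- stats::runif(spec$n_evrna, log2(50), log2(2000))
    m <- gen_block(n, spec$n_evrna, stratum, gs,
                   effects = et[et$block == "evrna", , drop = FALSE],
                   prefix = "RNA", base_log = base_log2,
                   log_base = 2, noise_sd = spec$noise_sd,
                   detection_rate = 1)
    # per-sample lane factor plus positive-control ladder probes
    lane <- 2^stats::rnorm(n, 0, 0.2)
    m <- m * lane
    ladder <- c(POS_A = 128, POS_B = 32, POS_C = 8,
                POS_D = 2, POS_E = 0.5, POS_F = 0.125)
    pos <- vapply(ladder, function(conc) {
      conc * 180 * lane * 2^stats::rnorm(n, 0, 0.05)
    }, numeric(n))
    cbind(m, pos)
  })
  rownames(evrna) <- ids

  clinical <- encode_clinical(patients)

  structure(
    list(patients = patients,
         clinical = clinical,
         peptide = omics_block(peptide, "peptide", "raw"),
         evrna = omics_block(evrna, "evrna", "raw"),
         spec = spec),
    class = "cohort"
  )
}

# Shared machinery for the two quantitative blocks. Detected values are
# log_base-normal around base_log, with planted features' means shifted by
# log(stratum fold multiplier); non-detections (peptides only) are exact
# zeros. Because shift acts on the log mean with unchanged sd, the ratio of
# expected detected values between strata equals the fold multiplier exactly.
gen_block <- function(n, p, stratum, group_sizes, effects, prefix,
                      base_log, log_base, noise_sd, detection_rate) {
  if (p == 0) {
    m <- matrix(numeric(0), nrow = n, ncol = 0)
    colnames(m) <- character(0)
    return(m)
  }
  nm <- sprintf("%s%04d", prefix, seq_len(p))
  if (nrow(effects) > 0) nm[seq_len(nrow(effects))] <- effects$feature
  s <- as.character(stratum)
  logf <- matrix(0, nrow = n, ncol = p)
  if (nrow(effects) > 0) {
    for (j in seq_len(nrow(effects))) {
      f <- stratum_folds(effects$fold[j], group_sizes)
      logf[, j] <- log(f[s], base = log_base)
    }
  }
  noise <- matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  m <- log_base^(matrix(base_log, n, p, byrow = TRUE) + logf + noise)
  if (detection_rate < 1) {
    det <- matrix(stats::runif(n * p) < detection_rate, n, p)
    m[!det] <- 0
  }
  colnames(m) <- nm
  m
}

#' Planted informative features of a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return named list (`clinical`, `peptide`, `evrna`) of the feature names
#'   planted with a real effect (fold change different from 1; for the
#'   clinical block, age and PSA when the spec encodes a cancer shift).
#' @export
planted_truth <- function(spec) {
  validate_synthetic_spec(spec)
  et <- spec$effect_table
  et <- et[et$fold != 1, , drop = FALSE]
  clin <- character(0)
  if (isTRUE(spec$clinical_params$cancer_shift)) clin <- c("age", "psa")
  list(
    clinical = clin,
    peptide = et$feature[et$block == "peptide"],
    evrna = et$feature[et$block == "evrna"]
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d patients | peptide %d | evrna %d | clinical %d>\n",
              nrow(x$patients), ncol(x$peptide$values),
              ncol(x$evrna$values), ncol(x$clinical$values)))
  invisible(x)
}
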