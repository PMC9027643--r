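# Small fixtures built in code: reduced synthetic specs and toy cohorts
# used across test files.

# a fast cohort: full stratum structure, few features
tiny_spec <- function(seed = 1L, ...) {
  synthetic_spec(
    group_sizes = c(NEC = 6, NEG_BIOPSY = 8, GS3_3 = 8, GS3_4 = 10,
                    GS4_3 = 6, GS4PLUS = 8),
    effect_table = data.frame(
      feature = c("PEP_SIG_UP", "PEP_SIG_DN", "RNA_SIG_UP"),
      block = c("peptide", "peptide", "evrna"),
      fold = c(4, 0.4, 3)
    ),
    n_peptides = 12, n_evrna = 8,
    seed = seed, ...
  )
}

# a cohort with no planted signal anywhere (null data)
null_spec <- function(seed = 1L) {
  cp <- default_clinical_params()
  cp$age_mean[] <- 67; cp$age_sd[] <- 8
  cp$psa_meanlog[] <- log(8); cp$psa_sdlog[] <- 0.5
  cp$cancer_shift <- FALSE
  synthetic_spec(
    effect_table = data.frame(feature = character(0), block = character(0),
                              fold = numeric(0)),
    n_peptides = 40, n_evrna = 20,
    clinical_params = cp,
    seed = seed
  )
}

# moderate complementary signals split across the three blocks, noisy
# enough that no single-block model saturates: the regime in which
# integrating blocks should win
complementary_spec <- function(seed = 1L) {
  synthetic_spec(
    effect_table = data.frame(
      feature = c("PEP_A", "PEP_B", "PEP_C", "RNA_A", "RNA_B", "RNA_C"),
      block = rep(c("peptide", "evrna"), each = 3),
      fold = c(2.5, 2.0, 0.5, 2.5, 2.0, 0.5)
    ),
    n_peptides = 120, n_evrna = 60,
    noise_sd = 2.0,
    seed = seed
  )
}

# exhaustive pairwise-concordance AUC oracle (ties counted 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force confusion-matrix net-benefit oracle
nb_oracle <- function(scores, labels, t) {
  tp <- 0; fp <- 0
  for (i in seq_along(scores)) {
    if (scores[i] >= t) {
      if (labels[i]) tp <- tp + 1 else fp <- fp + 1
    }
  }
  n <- length(scores)
  tp / n - (fp / n) * t / (1 - t)
}
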