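test_that("net benefit matches hand computation and boundary cases", {
  # n = 100, TP = 20, FP = 30 at t = 0.2: NB = 0.20 - 0.30 * 0.25 = 0.125
  scores <- c(rep(0.9, 50), rep(0.05, 50))
  labels <- c(rep(TRUE, 20), rep(FALSE, 30), rep(TRUE, 25), rep(FALSE, 25))
  nb <- net_benefit(scores, labels, 0.2)
  expect_equal(nb$nb, 0.125)
  expect_equal(nb$tp, 20); expect_equal(nb$fp, 30)
  # perfect classifier: NB = prevalence at any threshold
  lab2 <- runif(40) > 0.6
  perfect <- as.numeric(lab2)
  for (t in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(net_benefit(perfect, lab2, t)$nb, mean(lab2))
  }
  # biopsy nobody
  expect_equal(net_benefit(rep(0, 40), lab2, 0.3)$nb, 0)
  expect_error(net_benefit(scores, labels, 0), "strictly inside")
  expect_error(net_benefit(scores, labels, 1), "strictly inside")
})

test_that("net benefit agrees with the brute-force confusion-matrix oracle", {
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    s <- round(runif(n), 2)
    lab <- c(TRUE, runif(n - 1) > 0.5)
    for (t in seq(0.05, 0.95, by = 0.1)) {
      expect_equal(net_benefit(s, lab, t)$nb, nb_oracle(s, lab, t))
    }
  }
})

test_that("net benefit is bounded by prevalence and sNB by one", {
  set.seed(22)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    s <- runif(n); lab <- c(TRUE, runif(n - 1) > 0.4)
    t <- runif(1, 0.05, 0.95)
    nb <- net_benefit(s, lab, t)
    prev <- mean(lab)
    expect_lte(nb$nb, prev)
    expect_lte(snb(nb$nb, prev), 1)
    if (nb$fp == 0 && nb$tp == sum(lab)) expect_equal(nb$nb, prev)
  }
  expect_equal(snb(0.125, 0.25), 0.5)
  expect_equal(snb(0, 0.3), 0)
  expect_error(snb(0.1, 0), "prevalence")
})

test_that("treat-all policy biopsies on PSA >= 4 regardless of threshold", {
  lab <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  psa <- c(5.1, 3.9, 7.2, 4.0, 2.0, 8.8, 12, 3.2, 4.4, 6.0)
  # selected: psa >= 4 -> patients 1,3,4,6,7,9,10: TP = 4, FP = 3
  for (t in c(0.1, 0.4)) {
    nb <- treat_all_nb(psa, lab, t)
    expect_equal(nb$tp, 4); expect_equal(nb$fp, 3)
    expect_equal(nb$nb, 4 / 10 - (3 / 10) * t / (1 - t))
  }
  expect_equal(treat_all_nb(rep(10, 4), rep(TRUE, 4), 0.3)$nb, 1)
  expect_equal(treat_all_nb(rep(1, 4), rep(TRUE, 4), 0.3)$nb, 0)
})

test_that("prevalence-matched resampling hits the largest-remainder targets", {
  strata <- rep(gleason_levels(), times = c(23, 36, 31, 48, 25, 29))
  for (s in c(1, 99, 12345)) {
    idx <- cap_resample(strata, cap_prevalence(), n_out = 197, seed = s)
    expect_length(idx, 197)
    grp <- table(factor(ifelse(is_cancer(strata[idx]),
                               ifelse(ge_4_3(strata[idx]),
                                      ifelse(strata[idx] == "GS4PLUS", "GS8PLUS", "GS7"),
                                      ifelse(strata[idx] == "GS3_4", "GS7", "GS6")),
                               "NC"),
                        levels = c("NC", "GS6", "GS7", "GS8PLUS")))
    expect_equal(unname(grp), c(119, 47, 17, 14), ignore_attr = TRUE)
  }
  expect_identical(cap_resample(strata, seed = 7), cap_resample(strata, seed = 7))
  # required stratum missing from the cohort
  expect_error(cap_resample(rep(c("NEC", "GS3_3", "GS3_4"), 10)), "GS8PLUS")
  # proportions must sum to one
  expect_error(cap_prevalence(nc = 0.7), "sum to 1")
})

test_that("cohort already at target proportions keeps its shares", {
  strata <- rep(c("NEC", "GS3_3", "GS3_4", "GS4PLUS"), times = c(119, 47, 17, 14))
  idx <- cap_resample(strata, n_out = 197, seed = 3)
  tab <- table(urisk:::cap_group(strata)[idx]) / 197
  expect_equal(unname(tab[c("NC", "GS6", "GS7", "GS8PLUS")]),
               c(119, 47, 17, 14) / 197, ignore_attr = TRUE)
})

test_that("decision curves: coincidence, perfection, and treat-none", {
  strata <- rep(gleason_levels(), times = c(6, 8, 8, 10, 6, 8))
  n <- length(strata)
  set.seed(23)
  psa <- rlnorm(n, log(8), 0.5)
  soc <- runif(n)
  lab <- endpoint_labels(strata, "any_cancer")
  perfect <- as.numeric(lab)
  cur <- decision_curves(
    list(SoC = soc, Twin = soc, Perfect = perfect),
    strata, psa, endpoint = "any_cancer",
    thresholds = seq(0.1, 0.4, by = 0.1), B = 20, seed = 4
  )
  soc_rows <- cur[cur$model == "SoC", ]
  twin_rows <- cur[cur$model == "Twin", ]
  expect_equal(soc_rows$snb, twin_rows$snb)
  expect_equal(cur[cur$model == "Perfect", "snb"], rep(1, 4))
  expect_equal(cur[cur$model == "treat_none", "snb"], rep(0, 4))
  expect_true(all(cur$snb <= 1 + 1e-12))
})

test_that("a single resample reproduces a by-hand decision-curve computation", {
  strata <- rep(c("NEC", "NEG_BIOPSY", "GS3_3", "GS3_4", "GS4_3", "GS4PLUS"),
                times = c(3, 4, 4, 4, 2, 3))
  n <- length(strata)
  set.seed(24)
  scores <- runif(n); psa <- rlnorm(n, log(7), 0.4)
  thr <- c(0.15, 0.3)
  cur <- decision_curves(list(M = scores), strata, psa, endpoint = "ge_3_4",
                         thresholds = thr, n_out = 30, B = 1, seed = 55)
  # independent recomputation with the same derived resample
  idx <- cap_resample(strata, cap_prevalence(), 30,
                      seed = urisk:::derive_seed(55, 42L))
  lab <- endpoint_labels(strata, "ge_3_4")[idx]
  prev <- mean(lab)
  for (k in seq_along(thr)) {
    nb <- nb_oracle(scores[idx], lab, thr[k])
    expect_equal(cur[cur$model == "M", "nb"][k], nb)
    expect_equal(cur[cur$model == "M", "snb"][k], nb / prev)
  }
  ta <- treat_all_nb(psa[idx], lab, thr[1])
  expect_equal(cur[cur$model == "treat_all", "nb"][1], ta$nb)
})

test_that("biopsy net reduction follows the closed form", {
  expect_equal(biopsy_net_reduction(0.2, 0.2, 0.3), 0)
  # multiplier one at t = 0.5
  expect_equal(biopsy_net_reduction(0.27, 0.2, 0.5), 100 * 0.07)
  # delta 0.05 at t = 0.25 -> 15 per 100 patients
  expect_equal(biopsy_net_reduction(0.175, 0.125, 0.25), 15)
  expect_error(biopsy_net_reduction(0.2, 0.1, 0), "strictly inside")
  # linear in the net-benefit difference
  t <- 0.2
  expect_equal(biopsy_net_reduction(0.3, 0.1, t),
               2 * biopsy_net_reduction(0.2, 0.1, t))
  # strictly decreasing in t for fixed positive difference
  ts <- seq(0.05, 0.95, by = 0.05)
  red <- biopsy_net_reduction(0.2, 0.1, ts)
  expect_true(all(diff(red) < 0))
})

test_that("biopsy reduction table is relative to the standard-of-care model", {
  strata <- rep(gleason_levels(), times = c(6, 8, 8, 10, 6, 8))
  set.seed(25)
  n <- length(strata)
  cur <- decision_curves(
    list(SoC = runif(n), ExoSpec = runif(n)), strata, rlnorm(n, log(8), 0.4),
    endpoint = "any_cancer", thresholds = c(0.2, 0.3), B = 10, seed = 6
  )
  red <- biopsy_reduction_table(cur)
  expect_setequal(unique(red$model), c("ExoSpec", "treat_all"))
  exo <- red[red$model == "ExoSpec", ]
  nb_exo <- cur[cur$model == "ExoSpec", "nb"]
  nb_soc <- cur[cur$model == "SoC", "nb"]
  expect_equal(exo$reduction_per_100,
               (nb_exo - nb_soc) * (1 - c(0.2, 0.3)) / c(0.2, 0.3) * 100)
})
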