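make_pep_block <- function(m, ids = sprintf("P%02d", seq_len(nrow(m))),
                           feats = sprintf("pep%02d", seq_len(ncol(m)))) {
  rownames(m) <- ids; colnames(m) <- feats
  omics_block(m, "peptide", "raw")
}

test_that("peptide filter applies the inclusive 30% either-group rule", {
  strata <- c(rep("GS3_4", 10), rep("NEG_BIOPSY", 10))
  m <- matrix(0, 20, 3)
  m[1:3, 1] <- 5          # 3/10 cancer, 0/10 non-cancer -> retained (inclusive)
  m[c(1:2, 11:12), 2] <- 5 # 2/10 and 2/10 -> removed
  # column 3 all zeros -> removed
  blk <- make_pep_block(m)
  out <- filter_peptides(blk, strata)
  expect_equal(out$feature_names, "pep01")
  expect_error(filter_peptides(blk, rep("GS3_4", 20)), "non-cancer")
})

test_that("peptide filter matches a brute-force re-count oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:40) {
    n_ca <- sample(3:12, 1); n_nc <- sample(3:12, 1); p <- sample(1:15, 1)
    strata <- c(rep("GS4_3", n_ca), rep("NEC", n_nc))
    m <- matrix(rbinom((n_ca + n_nc) * p, 1, 0.3) * rexp((n_ca + n_nc) * p),
                n_ca + n_nc, p)
    colnames(m) <- sprintf("pep%02d", seq_len(p))
    blk <- make_pep_block(m, feats = colnames(m))
    out <- filter_peptides(blk, strata)
    keep_oracle <- vapply(seq_len(p), function(j) {
      d_ca <- sum(m[seq_len(n_ca), j] > 0)
      d_nc <- sum(m[n_ca + seq_len(n_nc), j] > 0)
      d_ca / n_ca >= 0.3 || d_nc / n_nc >= 0.3
    }, logical(1))
    expect_equal(out$feature_names, colnames(m)[keep_oracle])
    # never retains an all-zero column
    expect_true(all(colSums(out$values) > 0) || ncol(out$values) == 0)
    # idempotent
    twice <- filter_peptides(out, strata)
    expect_identical(twice$values, out$values)
  }
})

test_that("positive-control normalisation scales by geometric means", {
  # identical controls in every sample -> factors all 1
  v <- cbind(g1 = c(10, 20), g2 = c(5, 8), POS_A = c(4, 4), POS_B = c(9, 9))
  rownames(v) <- c("A", "B")
  out <- normalize_evrna(omics_block(v, "evrna", "raw"))
  expect_equal(out$values, log2(v[, 1:2] + 1))
  expect_equal(out$feature_names, c("g1", "g2"))
  expect_equal(out$scale, "log2")

  # sample B's control geometric mean is 2x sample A's -> B halved relative
  # to A before log2; cohort mean factor = (g + 2g)/2 / geomean_i
  v2 <- cbind(g1 = c(8, 8), POS_A = c(2, 4), POS_B = c(8, 16))
  rownames(v2) <- c("A", "B")
  out2 <- normalize_evrna(omics_block(v2, "evrna", "raw"))
  # geomeans: A = 4, B = 8; mean = 6; factors: A = 1.5, B = 0.75
  expect_equal(unname(out2$values[, "g1"]), c(log2(8 * 1.5 + 1), log2(8 * 0.75 + 1)))

  # zero endogenous count maps to log2(offset) = 0 at the default offset
  v3 <- cbind(g1 = c(0, 4), POS_A = c(3, 3))
  rownames(v3) <- c("A", "B")
  out3 <- normalize_evrna(omics_block(v3, "evrna", "raw"))
  expect_equal(unname(out3$values["A", "g1"]), 0)

  # all-zero positive controls -> error naming the sample
  v4 <- cbind(g1 = c(1, 1), POS_A = c(0, 3))
  rownames(v4) <- c("A", "B")
  expect_error(normalize_evrna(omics_block(v4, "evrna", "raw")), "A")
})

test_that("peptide log2 transform keeps zeros at zero", {
  m <- matrix(c(0, 1, 7, 3), 2, 2)
  blk <- make_pep_block(m)
  out <- log_transform_peptides(blk)
  expect_equal(unname(out$values), matrix(c(0, 1, 3, 2), 2, 2))
  m2 <- matrix(-1, 1, 1)
  rownames(m2) <- "P1"; colnames(m2) <- "x"
  blk2 <- omics_block(matrix(0, 1, 1, dimnames = list("P1", "x")), "peptide", "raw")
  blk2$values[1, 1] <- -1
  expect_error(log_transform_peptides(blk2), "negative")
})

test_that("design assembly restricts to the variant's blocks and partitions columns", {
  coh <- generate_cohort(tiny_spec(seed = 2))
  pep <- log_transform_peptides(filter_peptides(coh$peptide, coh$patients$stratum))
  rna <- normalize_evrna(coh$evrna)
  widths <- integer(0)
  for (v in c("SoC", "MassSpec", "ExoRNA")) {
    d <- assemble_design(coh$clinical, pep, rna, v)
    expect_true(all(d$column_block == switch(v, SoC = "clinical",
                                             MassSpec = "peptide", ExoRNA = "evrna")))
    widths <- c(widths, ncol(d$values))
  }
  full <- assemble_design(coh$clinical, pep, rna, "ExoSpec")
  expect_equal(sum(widths), ncol(full$values))
  expect_false(anyNA(full$values))
  expect_equal(unname(table(full$column_block)[c("clinical", "peptide", "evrna")]),
               widths, ignore_attr = TRUE)
  # raw-scale quantitative block refused
  expect_error(assemble_design(coh$clinical, coh$peptide, rna, "ExoSpec"), "log2")
  # row mismatch refused
  pep2 <- pep; pep2$values <- pep2$values[rev(seq_len(nrow(pep2$values))), ]
  expect_error(assemble_design(coh$clinical, pep2, rna, "ExoSpec"), "row-aligned")
})

test_that("DRE encoding is ordinal by default with a one-hot alternative", {
  pts <- data.frame(id = c("a", "b", "c", "d"), age = 65, psa = 6,
                    dre_size = c("Small", "Medium", "Large", "Unknown"),
                    urine_volume = 30)
  ord <- encode_clinical(pts)
  expect_equal(ncol(ord$values), 4)
  expect_equal(unname(ord$values[, "dre_size"]), c(1, 2, 3, 2))
  oh <- encode_clinical(pts, dre_encoding = "onehot")
  expect_equal(ncol(oh$values), 7)
  expect_equal(unname(oh$values[, "dre_unknown"]), c(0, 0, 0, 1))
})

test_that("cohort TSV round trip is lossless and malformed input is rejected", {
  coh <- generate_cohort(tiny_spec(seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients$id, coh$patients$id)
  expect_equal(back$patients$psa, coh$patients$psa)
  expect_equal(back$peptide$values, coh$peptide$values)
  expect_equal(back$evrna$values, coh$evrna$values)
  expect_equal(back$clinical$values, coh$clinical$values)

  # duplicate patient ID
  dir2 <- withr::local_tempdir()
  write_cohort(coh, dir2)
  pt <- readLines(file.path(dir2, "patients.tsv"))
  writeLines(c(pt, pt[2]), file.path(dir2, "patients.tsv"))
  expect_error(read_cohort(dir2), "duplicate")

  # non-numeric PSA names the row
  dir3 <- withr::local_tempdir()
  write_cohort(coh, dir3)
  pt <- read.delim(file.path(dir3, "patients.tsv"), colClasses = "character")
  pt$psa[3] <- "oops"
  write.table(pt, file.path(dir3, "patients.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_cohort(dir3), "row 3")
})
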