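#' Encode the clinical block
#'
#' Builds the numeric clinical [omics_block] from the patient table. The
#' default encoding keeps the four study variables as four columns (age,
#' PSA, DRE size, urine volume), scoring the DRE prostate-size impression
#' ordinally (Small = 1, Medium = 2, Large = 3) with Unknown imputed to
#' the median category; `dre_encoding = "onehot"` instead expands DRE into
#' four indicator columns with an explicit Unknown level.
#'
#' @param patients patient data.frame with columns `id`, `age`, `psa`,
#'   `dre_size`, `urine_volume`.
#' @param dre_encoding `"ordinal"` (default) or `"onehot"`.
#' @return clinical [omics_block] (scale `"raw"`).
#' @export
encode_clinical <- function(patients, dre_encoding = c("ordinal", "onehot")) {
  dre_encoding <- match.arg(dre_encoding)
  need <- c("id", "age", "psa", "dre_size", "urine_volume")
  if (!all(need %in% names(patients))) {
    stop("patients table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(patients$age <= 0)) stop("age must be > 0")
  if (any(patients$psa < 0)) stop("psa must be >= 0")
  lev <- c("Small", "Medium", "Large", "Unknown")
  bad <- setdiff(unique(patients$dre_size), lev)
  if (length(bad) > 0) stop("unknown dre_size level(s): ", paste(bad, collapse = ", "))
  if (dre_encoding == "ordinal") {
    dre_num <- c(Small = 1, Medium = 2, Large = 3, Unknown = 2)[patients$dre_size]
    m <- cbind(age = patients$age, psa = patients$psa,
               dre_size = unname(dre_num),
               urine_volume = patients$urine_volume)
  } else {
    oh <- vapply(lev, function(l) as.numeric(patients$dre_size == l),
                 numeric(nrow(patients)))
    colnames(oh) <- paste0("dre_", tolower(lev))
    m <- cbind(age = patients$age, psa = patients$psa, oh,
               urine_volume = patients$urine_volume)
  }
  uv <- m[, "urine_volume"]
  if (anyNA(uv)) m[is.na(uv), "urine_volume"] <- stats::median(uv, na.rm = TRUE)
  rownames(m) <- patients$id
  omics_block(m, "clinical", "raw")
}

#' A-priori peptide detection filter
#'
#' Retains a peptide if it was quantified at any level (raw intensity > 0)
#' in at least `min_frac` of cancer samples or at least `min_frac` of
#' non-cancer samples; the bound is inclusive. Column order is preserved
#' and the filter is idempotent.
#'
#' @param block raw-scale peptide [omics_block].
#' @param strata per-patient stratum vector (row-aligned with the block).
#' @param min_frac minimum detection fraction (default 0.30).
#' @return filtered peptide [omics_block].
#' @export
filter_peptides <- function(block, strata, min_frac = 0.30) {
  stopifnot(inherits(block, "omics_block"), block$block_kind == "peptide")
  if (block$scale != "raw") stop("filter_peptides requires the raw scale")
  s <- gleason_stratum(strata)
  if (length(s) != nrow(block$values)) stop("strata length must match block rows")
  ca <- is_cancer(s)
  if (!any(ca) || all(ca)) {
    stop("peptide filter undefined: need at least one cancer and one non-cancer sample")
  }
  det <- block$values > 0
  frac_ca <- colMeans(det[ca, , drop = FALSE])
  frac_nc <- colMeans(det[!ca, , drop = FALSE])
  keep <- frac_ca >= min_frac | frac_nc >= min_frac
  omics_block(block$values[, keep, drop = FALSE], "peptide", "raw")
}

#' Positive-control normalisation of EV-RNA counts
#'
#' Scales each sample by the ratio of the cohort-average positive-control
#' geometric mean to that sample's positive-control geometric mean (the
#' standard hybridisation-panel positive-control normalisation), then
#' log2-transforms with a pseudo-count offset. Positive-control columns are
#' dropped from the output.
#'
#' @param block raw-scale evrna [omics_block] of non-negative counts.
#' @param positive_controls names of the positive-control columns; defaults
#'   to columns matching `"^POS_"`.
#' @param offset pseudo-count added before log2 (default 1).
#' @return log2-scale evrna [omics_block] of endogenous probes.
#' @export
normalize_evrna <- function(block, positive_controls = NULL, offset = 1) {
  stopifnot(inherits(block, "omics_block"), block$block_kind == "evrna")
  if (block$scale != "raw") stop("normalize_evrna requires raw counts")
  v <- block$values
  if (any(v < 0)) stop("counts must be >= 0")
  if (is.null(positive_controls)) {
    positive_controls <- grep("^POS_", colnames(v), value = TRUE)
  }
  if (length(positive_controls) < 1) stop("need at least one positive-control column")
  if (!all(positive_controls %in% colnames(v))) {
    stop("positive-control column(s) not found: ",
         paste(setdiff(positive_controls, colnames(v)), collapse = ", "))
  }
  pos <- v[, positive_controls, drop = FALSE]
  geomean <- exp(rowMeans(log(pos)))
  if (any(!is.finite(geomean) | geomean <= 0)) {
    stop("sample(s) with zero positive-control counts: ",
         paste(rownames(v)[!is.finite(geomean) | geomean <= 0], collapse = ", "))
  }
  factor <- mean(geomean) / geomean
  endo <- v[, setdiff(colnames(v), positive_controls), drop = FALSE]
  out <- log2(endo * factor + offset)
  omics_block(out, "evrna", "log2")
}

#' Log2 transform of raw peptide intensities
#'
#' `x -> log2(x + 1)`, so zeros (not detected) stay exactly zero.
#'
#' @param block raw-scale peptide [omics_block].
#' @return log2-scale peptide [omics_block].
#' @export
log_transform_peptides <- function(block) {
  stopifnot(inherits(block, "omics_block"), block$block_kind == "peptide")
  if (block$scale != "raw") stop("log_transform_peptides requires the raw scale")
  if (any(block$values < 0)) stop("negative peptide intensity encountered")
  omics_block(log2(block$values + 1), "peptide", "log2")
}

#' Assemble a model design matrix
#'
#' Binds the requested blocks into the predictor matrix for one comparator
#' model variant: `SoC` uses the clinical block only, `MassSpec` the
#' (filtered, log2) peptide block only, `ExoRNA` the (normalised, log2)
#' EV-RNA block only, and `ExoSpec` all three. Column provenance is
#' recorded per column.
#'
#' @param clinical,peptide,evrna [omics_block]s, row-aligned; peptide and
#'   evrna must be on the log2 scale.
#' @param variant one of `"SoC"`, `"MassSpec"`, `"ExoRNA"`, `"ExoSpec"`.
#' @return object of class `design_matrix`: list with `values` (matrix),
#'   `column_block` (block kind per column), `variant`.
#' @export
assemble_design <- function(clinical, peptide, evrna,
                            variant = c("ExoSpec", "SoC", "MassSpec", "ExoRNA")) {
  variant <- match.arg(variant)
  blocks <- list(clinical = clinical, peptide = peptide, evrna = evrna)
  use <- switch(variant,
    SoC = "clinical", MassSpec = "peptide", ExoRNA = "evrna",
    ExoSpec = c("clinical", "peptide", "evrna")
  )
  ids <- rownames(blocks[[use[1]]]$values)
  for (b in use) {
    blk <- blocks[[b]]
    stopifnot(inherits(blk, "omics_block"))
    if (!identical(rownames(blk$values), ids)) {
      stop("blocks are not row-aligned (patient ID mismatch in ", b, " block)")
    }
    if (b %in% c("peptide", "evrna") && blk$scale != "log2") {
      stop(b, " block must be log2-transformed before design assembly")
    }
  }
  values <- do.call(cbind, lapply(blocks[use], function(b) b$values))
  colnames(values) <- unlist(lapply(blocks[use], function(b) b$feature_names),
                             use.names = FALSE)
  if (anyNA(values)) stop("design matrix contains missing values")
  column_block <- rep(use, times = vapply(blocks[use], function(b) ncol(b$values), 0L))
  structure(
    list(values = values, column_block = column_block, variant = variant),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix %s: %d patients x %d predictors (%s)>\n",
              x$variant, nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$column_block)),
                            table(x$column_block)), collapse = ", ")))
  invisible(x)
}

#' Variant names of the four comparator models
#' @return character vector.
#' @export
model_variants <- function() c("SoC", "MassSpec", "ExoRNA", "ExoSpec")
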