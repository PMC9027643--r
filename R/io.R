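# Cohort TSV round-trip: patients table plus one TSV matrix per block
# (first column `id`, header row of feature names) and a JSON sidecar with
# the generating spec, block scales, and planted truth.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_matrix_tsv <- function(values, path) {
  df <- data.frame(id = rownames(values), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(values))) df[[colnames(values)[j]]] <- fmt_num(values[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "id") stop("malformed header in ", path, ": first column must be 'id'")
  if (anyDuplicated(df$id)) {
    stop("duplicate patient ID(s) in ", path, ": ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1,
              dimnames = list(df$id, names(df)[-1]))
  for (j in seq_len(ncol(m))) {
    raw <- df[[j + 1]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & raw != "NA")
    if (length(bad) > 0) {
      stop("non-numeric value in ", path, ", column '", colnames(m)[j],
           "', row ", bad[1], " (id ", df$id[bad[1]], "): '", raw[bad[1]], "'")
    }
    m[, j] <- val
  }
  m
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes `patients.tsv`, `clinical.tsv`, `peptide.tsv`,
#' `evrna.tsv` and a `cohort.json` sidecar (spec, block scales, planted
#' truth) into `dir`. `read_cohort()` reads them back; the round trip is
#' lossless to full double precision.
#'
#' @param cohort a `cohort` as returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` returns a `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.tsv", "clinical.tsv", "peptide.tsv",
                            "evrna.tsv", "cohort.json"))
  names(paths) <- c("patients", "clinical", "peptide", "evrna", "sidecar")
  pt <- cohort$patients
  pt$age <- fmt_num(pt$age); pt$psa <- fmt_num(pt$psa)
  pt$urine_volume <- fmt_num(pt$urine_volume)
  utils::write.table(pt, paths["patients"], sep = "\t", quote = FALSE, row.names = FALSE)
  for (b in c("clinical", "peptide", "evrna")) {
    write_matrix_tsv(cohort[[b]]$values, paths[b])
  }
  sidecar <- list(
    scales = lapply(cohort[c("clinical", "peptide", "evrna")], function(b) b$scale),
    spec = if (!is.null(cohort$spec)) unclass(cohort$spec),
    planted_truth = if (!is.null(cohort$spec)) planted_truth(cohort$spec)
  )
  jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pt_path <- file.path(dir, "patients.tsv")
  pt <- utils::read.delim(pt_path, check.names = FALSE, colClasses = "character")
  need <- c("id", "age", "psa", "dre_size", "urine_volume", "stratum")
  if (!all(need %in% names(pt))) {
    stop("malformed header in ", pt_path, ": need columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(pt$id)) {
    stop("duplicate patient ID(s) in ", pt_path, ": ",
         paste(unique(pt$id[duplicated(pt$id)]), collapse = ", "))
  }
  for (col in c("age", "psa", "urine_volume")) {
    raw <- pt[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & raw != "NA")
    if (length(bad) > 0) {
      stop("non-numeric ", col, " in ", pt_path, ", row ", bad[1],
           " (id ", pt$id[bad[1]], "): '", raw[bad[1]], "'")
    }
    pt[[col]] <- val
  }
  gleason_stratum(pt$stratum)  # validates codes
  sidecar_path <- file.path(dir, "cohort.json")
  scales <- list(clinical = "raw", peptide = "raw", evrna = "raw")
  spec <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$scales)) scales[names(sc$scales)] <- sc$scales
    spec <- sc$spec
  }
  blocks <- list()
  for (b in c("clinical", "peptide", "evrna")) {
    m <- read_matrix_tsv(file.path(dir, paste0(b, ".tsv")))
    if (nrow(m) != nrow(pt) || !identical(rownames(m), pt$id)) {
      stop("row mismatch between patients.tsv and ", b, ".tsv")
    }
    blocks[[b]] <- omics_block(m, b, scales[[b]])
  }
  structure(
    c(list(patients = pt), blocks, list(spec = spec)),
    class = "cohort"
  )
}
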