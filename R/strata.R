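#' Gleason biopsy-outcome strata
#'
#' Patients are classified into six ordered biopsy-outcome strata: `NEC`
#' (no evidence of cancer: age-normal PSA, normal DRE, not biopsied),
#' `NEG_BIOPSY` (raised PSA, biopsy negative), and the Gleason-positive
#' strata `GS3_3`, `GS3_4`, `GS4_3`, `GS4PLUS` (Gleason >= 4+4). The two
#' non-biopsy-positive strata together form the "No Cancer" class.
#'
#' @param x character vector of stratum codes.
#' @return `gleason_stratum()` returns an ordered factor over the six levels.
#' @examples
#' s <- gleason_stratum(c("NEC", "GS3_4", "GS4PLUS"))
#' is_cancer(s)
#' @export
gleason_stratum <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), gleason_levels())
  if (length(bad) > 0) {
    stop("unknown Gleason stratum code(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = gleason_levels(), ordered = TRUE)
}

#' @rdname gleason_stratum
#' @export
gleason_levels <- function() {
  c("NEC", "NEG_BIOPSY", "GS3_3", "GS3_4", "GS4_3", "GS4PLUS")
}

#' @rdname gleason_stratum
#' @return `is_cancer()`, `ge_3_4()`, `ge_4_3()` return logical vectors.
#' @export
is_cancer <- function(x) {
  as.character(x) %in% c("GS3_3", "GS3_4", "GS4_3", "GS4PLUS")
}

#' @rdname gleason_stratum
#' @export
ge_3_4 <- function(x) {
  as.character(x) %in% c("GS3_4", "GS4_3", "GS4PLUS")
}

#' @rdname gleason_stratum
#' @export
ge_4_3 <- function(x) {
  as.character(x) %in% c("GS4_3", "GS4PLUS")
}

#' Continuous outcome encoding of the Gleason stratum
#'
#' Models are trained on a continuous 0-1 outcome reflecting dominant
#' Gleason pattern: no cancer (NEC or negative biopsy) is 0, Gleason
#' 3+3 and 3+4 are 0.5, and Gleason >= 4+3 is 1.
#'
#' @param stratum vector coercible via [gleason_stratum()].
#' @return numeric vector with values in \{0, 0.5, 1\}.
#' @examples
#' encode_outcome(c("NEC", "GS3_3", "GS4_3"))
#' @export
encode_outcome <- function(stratum) {
  s <- gleason_stratum(stratum)
  y <- ifelse(ge_4_3(s), 1, ifelse(is_cancer(s), 0.5, 0))
  as.numeric(y)
}

#' Binary endpoint labels from strata
#'
#' The three clinical endpoints used for model evaluation: any cancer on
#' biopsy, clinically significant disease (Gleason >= 3+4), and high-grade
#' disease (Gleason >= 4+3). Positive sets are nested.
#'
#' @param stratum vector coercible via [gleason_stratum()].
#' @param endpoint one of `"any_cancer"`, `"ge_3_4"`, `"ge_4_3"`.
#' @return logical vector, `TRUE` for endpoint-positive patients.
#' @export
endpoint_labels <- function(stratum, endpoint = c("any_cancer", "ge_3_4", "ge_4_3")) {
  endpoint <- match.arg(endpoint)
  s <- gleason_stratum(stratum)
  switch(endpoint,
    any_cancer = is_cancer(s),
    ge_3_4 = ge_3_4(s),
    ge_4_3 = ge_4_3(s)
  )
}

#' @rdname endpoint_labels
#' @export
endpoint_names <- function() c("any_cancer", "ge_3_4", "ge_4_3")
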