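#' Omics data block
#'
#' A patients-by-features numeric matrix tagged with its block kind and
#' value scale. Row names are patient IDs; column names are feature names.
#' Peptide blocks on the raw scale use exact zeros for "not detected".
#'
#' @param values numeric matrix (patients x features) with row and column
#'   names.
#' @param block_kind one of `"clinical"`, `"peptide"`, `"evrna"`.
#' @param scale one of `"raw"`, `"log2"`.
#' @return an object of class `omics_block`.
#' @export
omics_block <- function(values, block_kind = c("clinical", "peptide", "evrna"),
                        scale = c("raw", "log2")) {
  block_kind <- match.arg(block_kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have patient IDs as rownames and feature names as colnames")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature names in ", block_kind, " block")
  }
  if (block_kind == "peptide" && scale == "raw" && any(values < 0)) {
    stop("raw peptide intensities must be >= 0 (0 = not detected)")
  }
  structure(
    list(block_kind = block_kind, scale = scale,
         feature_names = colnames(values), values = values),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block %s [%s]: %d patients x %d features>\n",
              x$block_kind, x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)
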