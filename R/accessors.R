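#' @include AllClasses.R
NULL

#' Accessors for GenotypeData
#'
#' `dosages()` returns the SNPs x lines dosage matrix, `depths()` the
#' per-call read-depth matrix (or `NULL`), `lineInfo()` the per-line
#' metadata, `snpIds()`/`lineIds()` the row/column identifiers, and
#' `subgenomes()` the per-SNP subgenome letter (first character of the
#' chromosome name, `A` or `C`).
#'
#' @param x a [GenotypeData] object.
#' @return See the individual descriptions.
#' @export
dosages <- function(x) assay(x, "dosage")

#' @rdname dosages
#' @export
depths <- function(x) {
  if ("depth" %in% names(assays(x))) assay(x, "depth") else NULL
}

#' @rdname dosages
#' @export
lineInfo <- function(x) colData(x)

#' @rdname dosages
#' @export
snpIds <- function(x) rownames(x)

#' @rdname dosages
#' @export
lineIds <- function(x) colnames(x)

#' @rdname dosages
#' @export
subgenomes <- function(x) {
  substr(as.character(seqnames(rowRanges(x))), 1L, 1L)
}

setMethod("show", "GenotypeData", function(object) {
  d <- assay(object, "dosage")
  cat("GenotypeData:", nrow(d), "SNPs x", ncol(d), "lines\n")
  sg <- table(subgenomes(object))
  cat("  subgenomes:", paste(names(sg), sg, sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.1f%%; assays: %s\n",
              100 * mean(is.na(d)), paste(names(assays(object)), collapse = ", ")))
})
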