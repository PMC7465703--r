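#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

## ---------------------------------------------------------------------------
## GenotypeData: SNPs x lines dosage container
## ---------------------------------------------------------------------------

#' Genotype container for a panel of inbred lines
#'
#' `GenotypeData` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are biallelic SNPs (rowRanges carry chromosome, 1-based position and
#' the `ref`/`alt` alleles), columns are lines.  The `"dosage"` assay holds
#' alternate-allele counts in \{0, 1, 2, NA\}; the optional `"depth"` assay
#' holds per-call read depth.  Chromosome names start with the subgenome
#' letter (`A01`..`A10`, `C01`..`C09`).
#'
#' @param dosage integer matrix, SNPs x lines, values in 0/1/2/NA.
#' @param ranges `GRanges` of SNP positions (width 1) with metadata columns
#'   `ref` and `alt`; names are SNP identifiers (`S<chrom>_<pos>`).
#' @param lineInfo `DataFrame` (or data.frame) of per-line metadata with at
#'   least a `line_id` column; `ecotype` (`spring`/`winter`) is used by the
#'   phenotype simulator and downstream summaries.
#' @param depth optional numeric matrix of per-call read depth, same
#'   dimensions as `dosage`.
#'
#' @return A `GenotypeData` object.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("A01", IRanges::IRanges(c(100, 200), width = 1),
#'                              ref = c("A", "G"), alt = c("T", "C"))
#' names(gr) <- c("SA01_100", "SA01_200")
#' d <- matrix(c(0L, 2L, 1L, NA), nrow = 2,
#'             dimnames = list(names(gr), c("L1", "L2")))
#' g <- GenotypeData(d, gr, data.frame(line_id = c("L1", "L2")))
#' dosages(g)
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

#' @rdname GenotypeData-class
#' @export
GenotypeData <- function(dosage, ranges, lineInfo, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) rownames(dosage) <- names(ranges)
  if (is.null(colnames(dosage)) && !is.null(lineInfo$line_id))
    colnames(dosage) <- as.character(lineInfo$line_id)
  assays <- list(dosage = dosage)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    dimnames(depth) <- dimnames(dosage)
    assays$depth <- depth
  }
  cd <- DataFrame(lineInfo)
  rownames(cd) <- colnames(dosage)
  se <- SummarizedExperiment(assays = assays, rowRanges = ranges, colData = cd)
  new("GenotypeData", se)
}

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  rr <- rowRanges(object)
  if (length(rr)) {
    if (!all(c("ref", "alt") %in% names(S4Vectors::mcols(rr))))
      msg <- c(msg, "rowRanges must carry 'ref' and 'alt' columns")
    key <- paste(as.character(seqnames(rr)), start(rr))
    if (anyDuplicated(key))
      msg <- c(msg, "one record per (chromosome, position) required")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Parameter objects
## ---------------------------------------------------------------------------

#' Site-level SNP filter parameters
#'
#' Defaults reproduce the GBS filtering used for amphidiploid rapeseed
#' panels: MAF strictly greater than 0.03, per-site heterozygosity at most
#' 0.40 (read misalignment between homeologous A/C regions inflates apparent
#' heterozygosity), missingness at most 0.30, and genotype calls supported
#' by fewer than 10 reads masked to missing.
#'
#' @param mafMin minor-allele-frequency lower bound (strict `>`).
#' @param hetMax maximum per-site heterozygosity rate (inclusive).
#' @param missingMax maximum per-site missing fraction (inclusive).
#' @param depthMin minimum per-call read depth; calls below it are set to
#'   missing before the site-level statistics are computed.
#' @param depthPerSite if `TRUE`, apply `depthMin` to the per-site mean depth
#'   instead of masking individual calls.
#' @return A `FilterConfig` object.
#' @export
FilterConfig <- function(mafMin = 0.03, hetMax = 0.40, missingMax = 0.30,
                         depthMin = 10, depthPerSite = FALSE) {
  new("FilterConfig", mafMin = mafMin, hetMax = hetMax,
      missingMax = missingMax, depthMin = depthMin,
      depthPerSite = depthPerSite)
}

#' @rdname FilterConfig
#' @export
setClass("FilterConfig", representation(
  mafMin = "numeric", hetMax = "numeric", missingMax = "numeric",
  depthMin = "numeric", depthPerSite = "logical"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@mafMin < 0 || object@mafMin > 0.5)
    msg <- c(msg, "mafMin must be in [0, 0.5]")
  if (object@hetMax < 0 || object@hetMax > 1)
    msg <- c(msg, "hetMax must be in [0, 1]")
  if (object@missingMax < 0 || object@missingMax > 1)
    msg <- c(msg, "missingMax must be in [0, 1]")
  if (object@depthMin < 0) msg <- c(msg, "depthMin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Filtering report
#'
#' Records how many sites each criterion removed, in application order
#' (depth mask happens at call level and removes no whole site by itself;
#' site removal order is missing, then heterozygosity, then MAF).
#'
#' @slot input number of input sites.
#' @slot removed named integer vector of sites removed per criterion.
#' @slot output number of surviving sites.
#' @slot callsMasked number of genotype calls set to missing by the depth
#'   criterion.
#' @export
setClass("FilterReport", representation(
  input = "integer", removed = "integer", output = "integer",
  callsMasked = "integer"))

setValidity("FilterReport", function(object) {
  if (object@input - sum(object@removed) != object@output)
    "input - sum(removed) must equal output" else TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@input, "sites in,", object@output, "out\n")
  cat("  calls masked by depth:", object@callsMasked, "\n")
  for (nm in names(object@removed))
    cat(sprintf("  removed by %-8s %d\n", paste0(nm, ":"), object@removed[[nm]]))
})

#' Mixed-linear-model scan parameters
#'
#' @param nPcs number of principal components included as fixed covariates.
#' @param useCompression cluster lines into kinship groups and pick the group
#'   count maximizing the null REML likelihood over `n / compressionGrid`.
#' @param p3d estimate variance components once under the null and reuse them
#'   for every marker test; `FALSE` refits REML per marker (slow, used for
#'   oracle checks).
#' @param compressionGrid divisors of the line count tried as group counts.
#' @return An `MLMConfig` object.
#' @export
MLMConfig <- function(nPcs = 5, useCompression = TRUE, p3d = TRUE,
                      compressionGrid = c(1, 2, 4, 8)) {
  new("MLMConfig", nPcs = as.integer(nPcs), useCompression = useCompression,
      p3d = p3d, compressionGrid = as.numeric(compressionGrid))
}

#' @rdname MLMConfig
#' @export
setClass("MLMConfig", representation(
  nPcs = "integer", useCompression = "logical", p3d = "logical",
  compressionGrid = "numeric"))

## ---------------------------------------------------------------------------
## Result objects
## ---------------------------------------------------------------------------

#' Per-year association scan result
#'
#' @slot stats data.frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `effect` (phenotype units per alternate-allele copy), `p`,
#'   `r2_marker` (squared partial correlation given covariates under the
#'   fitted covariance), `r2_pheno` (share of total phenotypic variance,
#'   `effect^2 * 2p(1-p) / var(y)`), `flag`.
#' @slot varComp named numeric: `sigma_g2`, `sigma_e2` from the null fit.
#' @slot n number of lines used.
#' @slot year phenotype year label.
#' @slot compression chosen number of kinship groups.
#' @export
setClass("AssociationResult", representation(
  stats = "data.frame", varComp = "numeric", n = "integer",
  year = "character", compression = "integer"))

setMethod("show", "AssociationResult", function(object) {
  cat("AssociationResult (", object@year, "): ", nrow(object@stats),
      " SNPs, n = ", object@n, "\n", sep = "")
  cat(sprintf("  varcomp sigma_g2 = %.4g, sigma_e2 = %.4g; %d kinship groups\n",
              object@varComp[["sigma_g2"]], object@varComp[["sigma_e2"]],
              object@compression))
  top <- object@stats[order(object@stats$p), ][1, ]
  cat(sprintf("  top SNP %s p = %.3g effect = %.3g\n",
              top$snp_id, top$p, top$effect))
})

#' @rdname AssociationResult-class
#' @param object an `AssociationResult` or `CombinedResult`.
#' @export
assocStats <- function(object) object@stats

#' Cross-year combined association result
#'
#' @slot stats data.frame with per-SNP yearly p-values, their sum `S`, the
#'   Irwin-Hall density and CDF at `S` (`combined_p`), and the two
#'   significance flags.
#' @slot thresholds named numeric: `alpha`, `m`, `bonferroni`, `soft`.
#' @export
setClass("CombinedResult", representation(
  stats = "data.frame", thresholds = "numeric"))

setMethod("show", "CombinedResult", function(object) {
  th <- object@thresholds
  cat("CombinedResult:", nrow(object@stats), "SNPs over",
      sum(grepl("^p[0-9]+$", names(object@stats))), "years\n")
  cat(sprintf("  Bonferroni %.2g (= %.2g/%d, printed %s), soft %.4g\n",
              th[["bonferroni"]], th[["alpha"]], as.integer(th[["m"]]),
              formatC(signif(th[["bonferroni"]], 2), format = "f", digits = 7),
              th[["soft"]]))
  cat("  significant:", sum(object@stats$sig_bonferroni), "at Bonferroni,",
      sum(object@stats$sig_soft), "at soft threshold\n")
})

#' @rdname CombinedResult-class
#' @param object a `CombinedResult`.
#' @export
combinedStats <- function(object) object@stats

#' Principal-component decomposition of a relationship matrix
#'
#' @slot coords line x component coordinate matrix (eigenvectors scaled by
#'   the square root of their eigenvalues).
#' @slot percentVar percent of total variance per component, for all
#'   components of the decomposition.
#' @export
setClass("PCAResult", representation(
  coords = "matrix", percentVar = "numeric"))

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", nrow(object@coords), "lines,",
      ncol(object@coords), "components kept\n")
  k <- min(5L, ncol(object@coords))
  cat("  % variance:",
      paste(sprintf("PC%d %.1f", seq_len(k), object@percentVar[seq_len(k)]),
            collapse = ", "), "\n")
})

#' Linkage-disequilibrium decay summary
#'
#' One entry per scope (`A`, `C`, `genome`): the smoothed r-squared vs
#' distance curve, the decay length where it falls to the threshold (with
#' bootstrap SE), and the per-bin proportion of pairs above the threshold.
#'
#' @slot scopes named list; each element has `curve` (data.frame
#'   `dist`/`r2`), `length`, `se`, `flag`, `bins`, `n_pairs`.
#' @slot params named numeric: `frame`, `bin`, `threshold`.
#' @export
setClass("LDDecaySummary", representation(
  scopes = "list", params = "numeric"))

setMethod("show", "LDDecaySummary", function(object) {
  cat("LDDecaySummary (r2 threshold", object@params[["threshold"]], ")\n")
  for (nm in names(object@scopes)) {
    sc <- object@scopes[[nm]]
    if (is.na(sc$length))
      cat(sprintf("  %-6s undefined (%s), %d pairs\n", nm, sc$flag, sc$n_pairs))
    else
      cat(sprintf("  %-6s %.1f kb +/- %.1f (%d pairs)\n", nm,
                  sc$length / 1e3, sc$se / 1e3, sc$n_pairs))
  }
})
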