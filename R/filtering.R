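#' @include AllClasses.R
NULL

#' Per-site genotype statistics
#'
#' For every SNP: `missing_rate` = missing calls / lines; `het_rate` =
#' heterozygous calls / non-missing calls; `maf` = `min(p, 1 - p)` with `p`
#' the alternate-allele frequency over non-missing calls.  Sites with all
#' calls missing get `NA` for `maf` and `het_rate` and are flagged.
#'
#' @param geno a [GenotypeData] (or plain SNPs x lines dosage matrix).
#' @return data.frame with `snp_id`, `maf`, `het_rate`, `missing_rate`,
#'   `all_missing`.
#' @export
siteStats <- function(geno) {
  d <- if (is(geno, "GenotypeData")) dosages(geno) else as.matrix(geno)
  if (!nrow(d) || !ncol(d)) stop("empty genotype matrix")
  nl <- ncol(d)
  nmiss <- rowSums(is.na(d))
  nobs <- nl - nmiss
  nhet <- rowSums(d == 1L, na.rm = TRUE)
  p <- rowSums(d, na.rm = TRUE) / (2 * nobs)
  maf <- pmin(p, 1 - p)
  het <- nhet / nobs
  maf[nobs == 0L] <- NA_real_
  het[nobs == 0L] <- NA_real_
  data.frame(snp_id = rownames(d) %||% paste0("snp", seq_len(nrow(d))),
             maf = maf, het_rate = het, missing_rate = nmiss / nl,
             all_missing = nobs == 0L, row.names = NULL,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the site-level quality filters
#'
#' First, genotype calls with depth below `depthMin` are masked to missing
#' (when a depth assay is present).  Then sites are removed, in fixed order
#' and with each removal attributed to the first criterion that fails:
#' depth (sites pushed over the missingness bound by the depth mask alone),
#' missingness (`> missingMax` before the mask), heterozygosity
#' (`> hetMax`), and minor allele frequency (kept only if strictly
#' `> mafMin`).  The operation is idempotent: re-applying it to its own
#' output changes nothing.
#'
#' @param geno a [GenotypeData].
#' @param cfg a [FilterConfig].
#' @return list with `genotypes` (filtered [GenotypeData]) and `report`
#'   (a [FilterReport-class]).
#' @export
#' @examples
#' cfg <- SimulationConfig(chromosomes = data.frame(name = "A01", length = 2e6),
#'                         qtlSpec = data.frame(chrom = character(),
#'                                              pos = numeric(),
#'                                              effect = numeric()))
#' sim <- simulateGenotypes(cfg)
#' res <- applyFilters(sim$genotypes, FilterConfig())
#' res$report
applyFilters <- function(geno, cfg = FilterConfig()) {
  stopifnot(is(geno, "GenotypeData"), is(cfg, "FilterConfig"))
  d <- dosages(geno)
  dp <- depths(geno)
  masked <- 0L
  if (!is.null(dp) && cfg@depthMin > 0) {
    if (cfg@depthPerSite) {
      low <- rowMeans(dp, na.rm = TRUE) < cfg@depthMin
      masked <- sum(low) * ncol(d) - sum(is.na(d[low, , drop = FALSE]))
      d[low, ] <- NA_integer_
    } else {
      low <- dp < cfg@depthMin & !is.na(d)
      masked <- sum(low)
      d[low] <- NA_integer_
    }
  }
  st0 <- siteStats(dosages(geno))   # pre-mask missingness, for attribution
  st <- siteStats(d)
  over <- st$missing_rate > cfg@missingMax
  fail_missing <- st0$missing_rate > cfg@missingMax
  fail_depth <- over & !fail_missing
  fail_het <- !over & (st$all_missing | st$het_rate > cfg@hetMax)
  ## mafMin = 0 disables the criterion (otherwise strict ">" would still
  ## drop monomorphic sites)
  fail_maf <- !over & !fail_het & cfg@mafMin > 0 & !(st$maf > cfg@mafMin)
  keep <- !(fail_depth | fail_missing | fail_het | fail_maf)
  report <- new("FilterReport",
                input = nrow(d),
                removed = c(depth = sum(fail_depth),
                            missing = sum(fail_missing),
                            het = sum(fail_het), maf = sum(fail_maf)),
                output = sum(keep),
                callsMasked = as.integer(masked))
  if (!any(keep)) warning("no sites survive the filters")
  out <- geno[keep, ]
  SummarizedExperiment::assay(out, "dosage") <- d[keep, , drop = FALSE]
  list(genotypes = out, report = report)
}
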