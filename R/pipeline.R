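#' @include AllClasses.R simulate.R
NULL

#' End-to-end pipeline configuration
#'
#' @param outDir output directory (created if absent).
#' @param sim a [SimulationConfig] describing the cohort.
#' @param filter a [FilterConfig].
#' @param mlm an [MLMConfig].
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param soft soft combined-p threshold.
#' @param window annotation / co-location window in bp.
#' @param ldFrame,ldBin,ldThr,ldBoot LD stage parameters.
#' @param genesPerMb density of the simulated coordinate-scale gene models.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `PipelineConfig` object.
#' @export
PipelineConfig <- function(outDir, sim = SimulationConfig(),
                           filter = FilterConfig(), mlm = MLMConfig(),
                           alpha = 0.05, soft = 5e-4, window = 1e5,
                           ldFrame = 1.5e6, ldBin = 3e4, ldThr = 0.25,
                           ldBoot = 50L, genesPerMb = 2, seed = 1L) {
  new("PipelineConfig", outDir = outDir, sim = sim, filter = filter,
      mlm = mlm, alpha = alpha, soft = soft, window = window,
      ldFrame = ldFrame, ldBin = ldBin, ldThr = ldThr,
      ldBoot = as.integer(ldBoot), genesPerMb = genesPerMb,
      seed = as.integer(seed))
}

#' @rdname PipelineConfig
#' @export
setClass("PipelineConfig", representation(
  outDir = "character", sim = "SimulationConfig", filter = "FilterConfig",
  mlm = "MLMConfig", alpha = "numeric", soft = "numeric",
  window = "numeric", ldFrame = "numeric", ldBin = "numeric",
  ldThr = "numeric", ldBoot = "integer", genesPerMb = "numeric",
  seed = "integer"))

.stageError <- function(stage, e, fingerprint = "") {
  stop("pipeline stage '", stage, "' failed (", fingerprint, "): ",
       conditionMessage(e), call. = FALSE)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the eight stages in order — simulate, filter, structure,
#' per-year scans, cross-year combination, LD decay, window annotation,
#' cross-assembly mapping — writing every intermediate artifact under
#' `outDir` and a JSON manifest recording package version, seeds,
#' parameter values, the filter report and a content hash of every output
#' file.  A second run with the same config reproduces all outputs
#' byte-identically.
#'
#' The annotate stage uses coordinate-only gene models simulated along the
#' genotype chromosomes (window search needs no sequence); the crossmap
#' stage runs on the sequence-bearing toy assembly pair from
#' [simulateAnnotation()].
#'
#' @param config a [PipelineConfig].
#' @return the manifest, invisibly (a list).
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config@outDir, f)
  manifest <- list(package = "BnaGWAS",
                   version = as.character(utils::packageVersion("BnaGWAS")),
                   seed = config@seed, stages = list(), outputs = list())
  logmsg <- function(...) message("[pipeline] ", ...)

  ## 1. simulate -------------------------------------------------------------
  stage <- "simulate"
  logmsg(stage)
  sim <- tryCatch({
    simcfg <- config@sim
    simcfg@seed <- config@seed
    s <- simulateGenotypes(simcfg)
    ph <- simulatePhenotypes(s$genotypes, s$truth, simcfg)
    writeGenotypeVCF(s$genotypes, out("genotypes.vcf"))
    writePhenotypeTSV(ph, out("phenotypes.tsv"))
    jsonlite::write_json(
      list(causal = s$truth$causal,
           copy_rate = as.list(s$truth$copy_rate),
           decay_target = as.list(s$truth$decay_target)),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
    c(s, list(pheno = ph))
  }, error = function(e) .stageError(stage, e, "SimulationConfig"))
  manifest$stages$simulate <- list(
    n_lines = config@sim@nLines,
    n_snps = nrow(sim$genotypes),
    files = c("genotypes.vcf", "phenotypes.tsv", "truth.json"))

  ## 2. filter ---------------------------------------------------------------
  stage <- "filter"
  logmsg(stage)
  flt <- tryCatch(applyFilters(sim$genotypes, config@filter),
                  error = function(e) .stageError(stage, e, "genotypes.vcf"))
  geno <- flt$genotypes
  writeGenotypeVCF(geno, out("genotypes_filtered.vcf"))
  rep <- flt$report
  utils::write.table(
    data.frame(criterion = c("input", names(rep@removed), "output",
                             "calls_masked"),
               count = c(rep@input, unname(rep@removed), rep@output,
                         rep@callsMasked)),
    out("filter_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$filter <- list(
    input = rep@input, output = rep@output,
    removed = as.list(rep@removed), calls_masked = rep@callsMasked,
    files = c("genotypes_filtered.vcf", "filter_report.tsv"))

  ## 3. structure ------------------------------------------------------------
  stage <- "structure"
  logmsg(stage)
  str_res <- tryCatch({
    grm <- grmVarianceStandardized(geno)
    pca <- pcaGRM(grm, k = max(10L, config@mlm@nPcs))
    K <- kinshipCenteredIBS(geno)
    writeMatrixTSV(grm, out("grm.tsv"))
    writeMatrixTSV(K, out("kinship.tsv"))
    utils::write.table(
      data.frame(line_id = rownames(pca@coords), pca@coords,
                 check.names = FALSE),
      out("pca_coords.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    list(grm = grm, pca = pca, K = K)
  }, error = function(e) .stageError(stage, e, "genotypes_filtered.vcf"))
  manifest$stages$structure <- list(
    percent_var = round(str_res$pca@percentVar[1:5], 3),
    files = c("grm.tsv", "kinship.tsv", "pca_coords.tsv"))

  ## 4. per-year scans -------------------------------------------------------
  stage <- "scan"
  logmsg(stage)
  scans <- tryCatch(
    scanByYear(geno, sim$pheno, config@mlm),
    error = function(e) .stageError(stage, e, "phenotypes.tsv"))
  for (yr in names(scans))
    utils::write.table(scans[[yr]]@stats,
                       out(paste0("scan_", gsub("[^0-9A-Za-z]", "_", yr),
                                  ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$scan <- list(
    years = names(scans),
    varcomp = lapply(scans, function(s) as.list(s@varComp)),
    compression = lapply(scans, function(s) s@compression),
    files = paste0("scan_", gsub("[^0-9A-Za-z]", "_", names(scans)), ".tsv"))

  ## 5. combine --------------------------------------------------------------
  stage <- "combine"
  logmsg(stage)
  comb <- tryCatch(
    combineYears(scans, alpha = config@alpha, soft = config@soft),
    error = function(e) .stageError(stage, e, "scan tables"))
  utils::write.table(comb@stats, out("combined.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$combine <- list(
    thresholds = as.list(comb@thresholds),
    n_sig_bonferroni = sum(comb@stats$sig_bonferroni),
    n_sig_soft = sum(comb@stats$sig_soft),
    files = "combined.tsv")

  ## 6. LD -------------------------------------------------------------------
  stage <- "ld"
  logmsg(stage)
  ld <- tryCatch(
    summarizeLD(geno, frame = config@ldFrame, bin = config@ldBin,
                thr = config@ldThr, nBoot = config@ldBoot,
                seed = config@seed + 11L),
    error = function(e) .stageError(stage, e, "genotypes_filtered.vcf"))
  ld_json <- lapply(ld@scopes, function(sc)
    list(length_bp = sc$length, se_bp = sc$se, flag = sc$flag,
         n_pairs = sc$n_pairs))
  jsonlite::write_json(ld_json, out("ld_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(ld@scopes$genome$bins, out("ld_bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$ld <- list(summary = ld_json,
                             files = c("ld_summary.json", "ld_bins.tsv"))

  ## 7. annotate -------------------------------------------------------------
  stage <- "annotate"
  logmsg(stage)
  ann <- tryCatch({
    genes <- simulateGeneModels(config@sim@chromosomes,
                                genesPerMb = config@genesPerMb,
                                seed = config@seed + 23L)
    writeGeneModels(genes, out("gene_models.gff3"))
    sig <- comb@stats[comb@stats$sig_soft, , drop = FALSE]
    hits <- if (nrow(sig))
      genesInWindow(sig[, c("snp_id", "chrom", "pos")], genes,
                    window = config@window)
    else data.frame(snp_id = character(), gene_id = character(),
                    distance = numeric(), strand = character())
    utils::write.table(hits, out("annotation_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hits
  }, error = function(e) .stageError(stage, e, "combined.tsv"))
  manifest$stages$annotate <- list(
    n_hits = nrow(ann), files = c("gene_models.gff3", "annotation_hits.tsv"))

  ## 8. crossmap -------------------------------------------------------------
  stage <- "crossmap"
  logmsg(stage)
  cm <- tryCatch({
    bundle <- simulateAnnotation(config@sim, seed = config@seed + 31L)
    Biostrings::writeXStringSet(bundle$genome, out("assembly_source.fa"))
    Biostrings::writeXStringSet(bundle$assembly2, out("assembly_target.fa"))
    queries <- extractFlanks(bundle$genome, bundle$snps)
    mapped <- mapFlanks(queries, bundle$assembly2)
    expected <- mapThroughEdits(bundle$edits, queries$chrom, queries$pos)
    mapped$expected <- expected[match(mapped$snp_id, queries$snp_id)]
    mapped$concordant <- !is.na(mapped$position) &
      mapped$position == mapped$expected
    utils::write.table(mapped, out("crossmap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mapped
  }, error = function(e) .stageError(stage, e, "assembly pair"))
  manifest$stages$crossmap <- list(
    n_queries = nrow(cm), n_pass = sum(cm$pass),
    n_concordant = sum(cm$concordant),
    files = c("assembly_source.fa", "assembly_target.fa", "crossmap.tsv"))

  ## manifest ----------------------------------------------------------------
  files <- unlist(lapply(manifest$stages, function(s) s$files),
                  use.names = FALSE)
  manifest$outputs <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(out(f))))
  manifest$parameters <- list(
    filter = list(maf_min = config@filter@mafMin,
                  het_max = config@filter@hetMax,
                  missing_max = config@filter@missingMax,
                  depth_min = config@filter@depthMin),
    mlm = list(n_pcs = config@mlm@nPcs,
               compression = config@mlm@useCompression,
               p3d = config@mlm@p3d),
    thresholds = list(alpha = config@alpha, soft = config@soft,
                      window = config@window),
    ld = list(frame = config@ldFrame, bin = config@ldBin,
              threshold = config@ldThr))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
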