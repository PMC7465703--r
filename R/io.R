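#' @include AllClasses.R
NULL

#' Write genotypes as VCF
#'
#' Emits an uncompressed VCF v4.2 with one sample per line and `GT:DP`
#' genotype fields (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param geno a [GenotypeData].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypeVCF <- function(geno, path) {
  rr <- rowRanges(geno)
  d <- dosages(geno)
  dp <- depths(geno)
  if (is.null(dp)) dp <- matrix(".", nrow(d), ncol(d))
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  cells <- matrix(paste(gt, dp, sep = ":"), nrow(d), ncol(d))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=BnaGWAS",
    sprintf("##contig=<ID=%s,length=%d>",
            GenomeInfoDb::seqlevels(rr),
            GenomeInfoDb::seqlengths(rr)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(as.character(seqnames(rr)), start(rr), rownames(d),
                rr$ref, rr$alt, ".", "PASS", ".", "GT:DP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a GenotypeData object
#'
#' Keeps biallelic SNP records only (multi-allelic and indel records are
#' dropped with a message).  Genotypes are read from `GT` (any phasing
#' separator), per-call depth from `DP` when present.
#'
#' @param path VCF file (plain or bgzipped, as supported by vcfR).
#' @param lineInfo optional per-line metadata data.frame with `line_id`
#'   matching the VCF sample names.
#' @return A [GenotypeData].
#' @export
readGenotypeVCF <- function(path, lineInfo = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ok <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok))
    message("dropping ", sum(!ok), " non-biallelic-SNP records")
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  allele1 <- substr(gt, 1L, 1L)
  allele2 <- substr(gt, 3L, 3L)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  known <- allele1 %in% c("0", "1") & allele2 %in% c("0", "1")
  dos[known] <- as.integer(allele1[known]) + as.integer(allele2[known])
  dp <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[ok, ,
                                                                 drop = FALSE]
    dp[is.na(dp)] <- 0
  }
  chrom <- fix[ok, "CHROM"]; pos <- as.integer(fix[ok, "POS"])
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                ref = ref[ok], alt = alt[ok])
  ids <- fix[ok, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("S", chrom, "_", pos)[is.na(ids) | ids == "."]
  names(gr) <- ids
  rownames(dos) <- ids
  if (is.null(lineInfo))
    lineInfo <- data.frame(line_id = colnames(dos), stringsAsFactors = FALSE)
  GenotypeData(dos, gr, lineInfo, depth = dp)
}

#' Read and write the phenotype table
#'
#' Tab-separated table with columns `line_id`, `ecotype`, `year`,
#' `gsl_umol_g` (glucosinolate content, umol per g fresh weight).
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @return `writePhenotypeTSV()` returns `path` invisibly;
#'   `readPhenotypeTSV()` returns the validated data.frame.
#' @export
writePhenotypeTSV <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTSV
#' @export
readPhenotypeTSV <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "year", "gsl_umol_g")
  if (!all(need %in% names(ph)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (any(ph$gsl_umol_g <= 0))
    stop("glucosinolate values must be positive")
  if (anyDuplicated(ph[c("line_id", "year")]))
    stop("(line_id, year) pairs must be unique")
  ph
}

#' Write gene models as GFF3
#'
#' @param genes GRanges with `gene_id`.
#' @param path output file.
#' @param cds optional list/`SimpleList` of per-gene CDS GRanges (with
#'   `phase`), written as child `CDS` features.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path, cds = NULL) {
  g <- genes
  g$type <- "gene"
  g$ID <- g$gene_id
  feats <- list(g)
  if (!is.null(cds)) {
    for (id in names(cds)) {
      cc <- cds[[id]]
      cc$type <- "CDS"
      cc$ID <- paste0(id, ".cds", seq_along(cc))
      cc$Parent <- id
      feats[[length(feats) + 1L]] <- cc
    }
  }
  feats <- lapply(feats, function(x) {
    mc <- S4Vectors::mcols(x)
    keep <- intersect(c("type", "ID", "Parent", "gene_id", "phase"), names(mc))
    S4Vectors::mcols(x) <- mc[, keep, drop = FALSE]
    x
  })
  all <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` and (optionally) `CDS` features; CDS
#'   features must name their gene through `Parent` (directly or via an
#'   mRNA whose `Parent` is the gene).
#' @return list with `genes` (GRanges with `gene_id`) and `cds`
#'   (`SimpleList` of GRanges keyed by gene id, with `phase`).
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  genes$gene_id <- if (!is.null(genes$ID)) genes$ID else genes$gene_id
  cds_feats <- gff[gff$type == "CDS"]
  cds <- list()
  if (length(cds_feats)) {
    parent <- vapply(as.list(cds_feats$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, "")
    ## resolve mRNA parents to genes if present
    mrna <- gff[gff$type == "mRNA"]
    if (length(mrna)) {
      mp <- vapply(as.list(mrna$Parent), function(p)
        if (length(p)) p[[1L]] else NA_character_, "")
      names(mp) <- mrna$ID
      hit <- parent %in% names(mp)
      parent[hit] <- mp[parent[hit]]
    }
    parent <- sub("\\.cds[0-9]+$", "", parent)
    for (id in unique(parent)) {
      cc <- cds_feats[parent == id]
      cc$gene_id <- id
      cds[[id]] <- cc
    }
  }
  list(genes = genes, cds = S4Vectors::SimpleList(cds))
}

#' Write a numeric line x line matrix as TSV with identifiers
#' @param m matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
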