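#' @include AllClasses.R
NULL

#' Genes within a window around SNPs
#'
#' Returns every gene whose span intersects `[pos - window, pos + window]`
#' for each query SNP.  Distance is 0 when the SNP lies inside the gene
#' span; otherwise it is the signed gap to the nearest gene edge, negative
#' when the SNP is upstream of the gene start (plus-strand orientation of
#' the coordinate axis).  Hits are sorted by absolute distance within each
#' SNP.
#'
#' @param snps GRanges of SNP positions (named), or a data.frame with
#'   `snp_id`, `chrom`, `pos`.
#' @param genes GRanges of gene spans with a `gene_id` column.
#' @param window half-window in bp (default 100,000).
#' @return data.frame with `snp_id`, `gene_id`, `distance`, `strand`.
#'   SNPs on chromosomes absent from the gene set yield no rows (with a
#'   warning).
#' @export
genesInWindow <- function(snps, genes, window = 1e5) {
  if (is.data.frame(snps)) {
    gr <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L))
    names(gr) <- snps$snp_id
    snps <- gr
  }
  unknown <- !as.character(seqnames(snps)) %in%
    as.character(GenomicRanges::seqnames(genes))
  if (any(unknown))
    warning(sum(unknown), " SNP(s) on chromosomes without gene models")
  win <- suppressWarnings(GenomicRanges::resize(
    snps, width = 2 * window + 1L, fix = "center"))
  win <- GenomicRanges::trim(win)
  hits <- GenomicRanges::findOverlaps(win, genes, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(snp_id = character(), gene_id = character(),
                      distance = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pos <- start(snps)[qi]
  gs <- start(genes)[si]; ge <- end(genes)[si]
  dist <- ifelse(pos < gs, pos - gs, ifelse(pos > ge, pos - ge, 0))
  out <- data.frame(snp_id = names(snps)[qi],
                    gene_id = genes$gene_id[si],
                    distance = dist,
                    strand = as.character(strand(genes))[si],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$snp_id, names(snps)), abs(out$distance)), ]
  rownames(out) <- NULL
  out
}

## genomic coordinates of one codon of a CDS, in translation order
.codonCoords <- function(cds_gr, cdsPos) {
  strand <- as.character(strand(cds_gr))[1L]
  segs <- if (strand == "+") cds_gr[order(start(cds_gr))]
          else cds_gr[order(-start(cds_gr))]
  ## per-base genomic positions in translation order
  posl <- lapply(seq_along(segs), function(i) {
    p <- start(segs)[i]:end(segs)[i]
    if (strand == "-") rev(p) else p
  })
  allpos <- unlist(posl)
  codon <- (cdsPos - 1L) %/% 3L
  idx <- codon * 3L + 1:3
  if (max(idx) > length(allpos)) return(NULL)
  list(pos = allpos[idx], strand = strand, within = cdsPos - codon * 3L)
}

#' Classify the coding effect of a SNP within a gene
#'
#' A SNP outside every gene span is `intergenic`; inside the gene span but
#' outside the CDS it is `intronic`; inside the CDS the reference and
#' alternate codons are translated (strand- and phase-aware, standard
#' genetic code) and the call is `synonymous` when the amino acids match,
#' `missense` when they differ, and `other` for stop gain/loss, start loss,
#' or a CDS whose total length is not divisible by 3 (warned).
#'
#' @param snp one-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param geneId gene identifier to classify against.
#' @param models gene models as returned by [readGeneModels()] or
#'   [simulateAnnotation()] (list with `genes` and `cds`).
#' @param genome DNAStringSet covering the gene.
#' @return character effect class: `intergenic`, `intronic`, `synonymous`,
#'   `missense`, or `other`.
#' @export
classifyEffect <- function(snp, geneId, models, genome) {
  genes <- models$genes
  g <- genes[genes$gene_id == geneId]
  if (!length(g)) stop("unknown gene: ", geneId)
  pos <- as.integer(snp$pos); chrom <- as.character(snp$chrom)
  if (chrom != as.character(seqnames(g)) ||
      pos < start(g) || pos > end(g)) return("intergenic")
  cds <- models$cds[[geneId]]
  if (is.null(cds) || !length(cds)) return("intronic")
  if (sum(GenomicRanges::width(cds)) %% 3L != 0L) {
    warning("CDS length of ", geneId, " not divisible by 3")
    return("other")
  }
  inCds <- any(pos >= start(cds) & pos <= end(cds))
  if (!inCds) return("intronic")
  strand <- as.character(strand(cds))[1L]
  segs <- if (strand == "+") cds[order(start(cds))] else cds[order(-start(cds))]
  cdsPos <- 0L
  for (i in seq_along(segs)) {
    s <- start(segs)[i]; e <- end(segs)[i]
    if (pos >= s && pos <= e) {
      cdsPos <- cdsPos + (if (strand == "+") pos - s + 1L else e - pos + 1L)
      break
    }
    cdsPos <- cdsPos + (e - s + 1L)
  }
  cc <- .codonCoords(cds, cdsPos)
  if (is.null(cc)) return("other")
  seq <- genome[[chrom]]
  base_at <- function(p) as.character(Biostrings::subseq(seq, p, p))
  bases <- vapply(cc$pos, base_at, "")
  if (strand == "-")
    bases <- vapply(bases, function(b) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(b))), "")
  refCodon <- paste(bases, collapse = "")
  refBase <- base_at(pos)
  if (!is.null(snp$ref) && !identical(refBase, as.character(snp$ref)))
    warning("reference base mismatch at ", chrom, ":", pos)
  altBase <- as.character(snp$alt)
  if (strand == "-")
    altBase <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(altBase)))
  altBases <- bases
  altBases[cc$within] <- altBase
  altCodon <- paste(altBases, collapse = "")
  aaRef <- as.character(Biostrings::translate(Biostrings::DNAString(refCodon),
                                              no.init.codon = TRUE))
  aaAlt <- as.character(Biostrings::translate(Biostrings::DNAString(altCodon),
                                              no.init.codon = TRUE))
  if (aaRef == aaAlt) return("synonymous")
  if (aaRef == "*" || aaAlt == "*") return("other")
  if (cdsPos <= 3L && aaRef == "M") return("other")   # start loss
  "missense"
}

#' Annotate SNPs with window hits and coding effects
#'
#' Convenience wrapper combining [genesInWindow()] and (when a genome
#' sequence is supplied) [classifyEffect()] for the genes the SNP falls in.
#'
#' @param snps GRanges with `ref`/`alt` (as from [simulateAnnotation()]) or
#'   data.frame with `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param models gene models (list with `genes`, `cds`).
#' @param genome optional DNAStringSet; without it effects of intragenic
#'   SNPs are reported as `NA`.
#' @param window half-window in bp.
#' @return data.frame of hits with an `effect` column.
#' @export
annotateSnps <- function(snps, models, genome = NULL, window = 1e5) {
  if (is(snps, "GRanges")) {
    df <- data.frame(snp_id = names(snps),
                     chrom = as.character(seqnames(snps)),
                     pos = start(snps),
                     ref = snps$ref %||% NA_character_,
                     alt = snps$alt %||% NA_character_,
                     stringsAsFactors = FALSE)
  } else df <- snps
  hits <- genesInWindow(df, models$genes, window = window)
  hits$effect <- NA_character_
  hits$effect[hits$distance != 0] <- "intergenic"
  inside <- which(hits$distance == 0)
  if (!is.null(genome)) {
    for (i in inside) {
      row <- df[df$snp_id == hits$snp_id[i], ]
      hits$effect[i] <- classifyEffect(row, hits$gene_id[i], models, genome)
    }
  }
  hits
}
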