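#' @include AllClasses.R
NULL

#' Simulate a toy annotation bundle: genome, gene models, paired assembly
#'
#' Emits a small random genome (one sequence per toy chromosome), a set of
#' gene models with two-exon CDS structures, a set of SNP positions at
#' controlled offsets from genes, and a second "assembly" derived from the
#' first by a configured list of edits (insertions, deletions,
#' substitutions) with a recorded coordinate map.  The bundle is the
#' sequence-bearing companion of the coordinate-scale genotype simulation:
#' window annotation, coding-effect classification and flank-based
#' cross-assembly mapping are all testable on it.
#'
#' @param config a [SimulationConfig]; only its `seed` is used unless
#'   `seed` is given.
#' @param chromLengths named integer vector of toy chromosome lengths (bp).
#' @param geneStarts optional named list (per chromosome) of gene start
#'   positions; by default genes are placed on a regular grid.
#' @param geneLength gene span (bp); the CDS is two exons inside it.
#' @param nGenes genes per chromosome when `geneStarts` is `NULL`.
#' @param snpOffsets offsets (bp) of emitted SNP positions relative to the
#'   start of the first gene on each chromosome (0 = inside the gene).
#' @param edits data.frame of edits applied to derive the second assembly:
#'   columns `chrom`, `pos` (1-based position in the source assembly at
#'   which the edit applies), `type` (`ins`, `del`, `sub`), `length`.
#'   `NULL` applies a default single insertion plus scattered substitutions;
#'   use `data.frame()` for zero edits.
#' @param seed overrides `config@seed`.
#' @return list: `genome` (DNAStringSet), `genes` (GRanges with `gene_id`,
#'   `strand`), `cds` (GRangesList per gene, with `phase`), `snps`
#'   (GRanges with `ref`/`alt` and names), `assembly2` (DNAStringSet),
#'   `edits` (data.frame as above).
#' @export
simulateAnnotation <- function(config = SimulationConfig(),
                               chromLengths = c(A01 = 300000L, C01 = 300000L),
                               geneStarts = NULL, geneLength = 3000L,
                               nGenes = 5L,
                               snpOffsets = c(1500L, 50000L, 200000L),
                               edits = NULL, seed = NULL) {
  if (is.null(seed)) seed <- config@seed
  set.seed(seed + 7919L)
  bases <- c("A", "C", "G", "T")
  genome <- Biostrings::DNAStringSet(vapply(chromLengths, function(len) {
    paste(sample(bases, len, replace = TRUE), collapse = "")
  }, ""))
  names(genome) <- names(chromLengths)

  gene_list <- list(); cds_list <- list(); gid <- 0L
  for (chr in names(chromLengths)) {
    starts <- if (!is.null(geneStarts)) geneStarts[[chr]]
              else round(seq(20000L, chromLengths[[chr]] - geneLength - 20000L,
                             length.out = nGenes))
    for (s in starts) {
      gid <- gid + 1L
      id <- sprintf("gene%03d", gid)
      strand <- if (gid %% 2L == 0L) "-" else "+"
      g <- GRanges(chr, IRanges(s, s + geneLength - 1L), strand = strand,
                   gene_id = id)
      ## two CDS exons; total length divisible by 3
      e1 <- IRanges(s + 100L, s + 100L + 299L)            # 300 bp
      e2 <- IRanges(s + 1000L, s + 1000L + 599L)          # 600 bp
      cds <- GRanges(chr, c(e1, e2), strand = strand, gene_id = id)
      ## phase per segment in translation order
      ord <- if (strand == "+") 1:2 else 2:1
      w <- cumsum(c(0L, GenomicRanges::width(cds)[ord]))[1:2]
      ph <- (3L - (w %% 3L)) %% 3L
      cds$phase <- NA_integer_
      cds$phase[ord] <- ph
      gene_list[[id]] <- g
      cds_list[[id]] <- cds
    }
  }
  genes <- suppressWarnings(do.call(c, unname(gene_list)))
  cds <- S4Vectors::SimpleList(cds_list)

  ## SNPs at configured offsets from the first gene of each chromosome
  snp_list <- list()
  for (chr in names(chromLengths)) {
    gchr <- genes[as.character(seqnames(genes)) == chr]
    base <- min(start(gchr))
    pos <- base + snpOffsets
    pos <- pos[pos >= 1 & pos <= chromLengths[[chr]]]
    ref <- vapply(pos, function(p)
      as.character(Biostrings::subseq(genome[[chr]], p, p)), "")
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    gr <- GRanges(chr, IRanges(pos, width = 1L), ref = ref, alt = unname(alt))
    names(gr) <- paste0("S", chr, "_", pos)
    snp_list[[chr]] <- gr
  }
  snps <- suppressWarnings(do.call(c, unname(snp_list)))

  if (is.null(edits)) {
    edits <- data.frame(
      chrom = names(chromLengths)[1L],
      pos = c(10000L, 150000L),
      type = c("ins", "sub"),
      length = c(500L, 1L), stringsAsFactors = FALSE)
  }
  assembly2 <- applyEdits(genome, edits, seed = seed + 27L)

  list(genome = genome, genes = genes, cds = cds, snps = snps,
       assembly2 = assembly2, edits = edits)
}

#' Apply an edit list to an assembly
#'
#' Edits are interpreted on source coordinates: an insertion of `length`
#' bases is placed immediately before `pos`; a deletion removes
#' `[pos, pos + length - 1]`; a substitution replaces those bases with
#' different ones.
#'
#' @param genome DNAStringSet.
#' @param edits data.frame with `chrom`, `pos`, `type`, `length`.
#' @param seed seed for the inserted/substituted sequence content.
#' @return DNAStringSet of the edited assembly.
#' @export
applyEdits <- function(genome, edits, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- as.character(genome)
  if (nrow(edits) == 0L) return(Biostrings::DNAStringSet(out))
  for (chr in unique(edits$chrom)) {
    s <- out[[chr]]
    ed <- edits[edits$chrom == chr, , drop = FALSE]
    ed <- ed[order(-ed$pos), , drop = FALSE]    # apply right to left
    for (k in seq_len(nrow(ed))) {
      p <- ed$pos[k]; len <- ed$length[k]
      if (ed$type[k] == "ins") {
        insert <- paste(sample(bases, len, replace = TRUE), collapse = "")
        s <- paste0(substr(s, 1L, p - 1L), insert, substr(s, p, nchar(s)))
      } else if (ed$type[k] == "del") {
        s <- paste0(substr(s, 1L, p - 1L), substr(s, p + len, nchar(s)))
      } else if (ed$type[k] == "sub") {
        orig <- strsplit(substr(s, p, p + len - 1L), "")[[1L]]
        repl <- vapply(orig, function(b) sample(setdiff(bases, b), 1L), "")
        s <- paste0(substr(s, 1L, p - 1L), paste(repl, collapse = ""),
                    substr(s, p + len, nchar(s)))
      } else stop("unknown edit type: ", ed$type[k])
    }
    out[[chr]] <- s
  }
  Biostrings::DNAStringSet(out)
}

#' Map source-assembly positions through an edit list
#'
#' @param edits edit data.frame as in [applyEdits()].
#' @param chrom chromosome name(s).
#' @param pos source positions (1-based).
#' @return integer target positions; `NA` for positions inside a deletion.
#'   With zero edits the map is the identity.
#' @export
mapThroughEdits <- function(edits, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- as.numeric(pos)
  for (i in seq_len(n)) {
    shift <- 0
    ed <- edits[edits$chrom == chrom[i], , drop = FALSE]
    for (k in seq_len(nrow(ed))) {
      if (ed$type[k] == "ins" && ed$pos[k] <= pos[i]) shift <- shift + ed$length[k]
      if (ed$type[k] == "del") {
        if (pos[i] >= ed$pos[k] && pos[i] < ed$pos[k] + ed$length[k]) {
          out[i] <- NA; break
        }
        if (ed$pos[k] + ed$length[k] <= pos[i]) shift <- shift - ed$length[k]
      }
    }
    if (!is.na(out[i])) out[i] <- pos[i] + shift
  }
  out
}

#' Simulate coordinate-only gene models along real-scale chromosomes
#'
#' For window annotation at genotype-simulation scale no sequence is needed;
#' this places gene spans (no CDS) at a configured density along the given
#' chromosomes.
#'
#' @param chromosomes data.frame with `name` and `length` (bp).
#' @param genesPerMb average gene density.
#' @param geneLength mean gene span (bp).
#' @param seed integer seed.
#' @return GRanges with `gene_id`.
#' @export
simulateGeneModels <- function(chromosomes, genesPerMb = 2, geneLength = 4000L,
                               seed = 1L) {
  set.seed(seed)
  grl <- lapply(seq_len(nrow(chromosomes)), function(i) {
    len <- chromosomes$length[i]
    n <- max(1L, round(len * genesPerMb / 1e6))
    s <- sort(sample.int(len - geneLength, n))
    GRanges(chromosomes$name[i], IRanges(s, width = geneLength),
            strand = sample(c("+", "-"), n, replace = TRUE))
  })
  gr <- suppressWarnings(do.call(c, grl))
  gr$gene_id <- sprintf("gene%05d", seq_along(gr))
  gr
}
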