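#' @include AllClasses.R
NULL

#' Extract SNP flanking-sequence queries
#'
#' A 101-base window centred on each SNP (50 bp upstream, the site, 50 bp
#' downstream) is cut from the source assembly.  Windows overlapping a
#' chromosome end are truncated and flagged.
#'
#' @param assembly DNAStringSet of the source assembly.
#' @param snps GRanges (named) or data.frame with `snp_id`, `chrom`, `pos`.
#' @param flank flank length on each side (default 50).
#' @return data.frame with `snp_id`, `chrom`, `pos`, `start`, `end`,
#'   `center_offset` (SNP position within the query), `truncated`, `seq`.
#' @export
extractFlanks <- function(assembly, snps, flank = 50L) {
  if (is(snps, "GRanges"))
    snps <- data.frame(snp_id = names(snps),
                       chrom = as.character(seqnames(snps)),
                       pos = start(snps), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(snps)), function(i) {
    chrom <- snps$chrom[i]; pos <- snps$pos[i]
    if (!chrom %in% names(assembly)) stop("unknown chromosome: ", chrom)
    len <- Biostrings::width(assembly[chrom])
    if (pos < 1L || pos > len)
      stop("position ", pos, " off chromosome ", chrom)
    s <- max(1L, pos - flank); e <- min(len, pos + flank)
    data.frame(snp_id = snps$snp_id[i], chrom = chrom, pos = pos,
               start = s, end = e, center_offset = pos - s + 1L,
               truncated = (e - s + 1L) < (2L * flank + 1L),
               seq = as.character(Biostrings::subseq(assembly[[chrom]], s, e)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Karlin-Altschul ungapped lambda for a match/mismatch score scheme with
## uniform base composition: solve sum p_i p_j exp(lambda * s_ij) = 1.
.kaLambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

#' Map a flanking-sequence query onto a target assembly
#'
#' Best local alignment of the query to each target sequence (match +1,
#' mismatch -2, gap open -5, gap extend -2); the e-value comes from the
#' ungapped Karlin-Altschul formula `E = K m n exp(-lambda S)` with
#' `lambda` solved for the score scheme, `K = 0.621` (the standard
#' nucleotide-search constant for +1/-2), `m` the query length and `n` the
#' total target length.  The SNP position is transferred through the
#' alignment column holding the query centre.  A hit passes iff alignment
#' length > 90 and e-value < 1e-40 (both strict).  Ties in best score
#' across target sequences are rejected as ambiguous.
#'
#' @param query one row of [extractFlanks()] output (or a list with `seq`,
#'   `center_offset`, `snp_id`).
#' @param target DNAStringSet of the target assembly.
#' @param match,mismatch,gapOpen,gapExtend local-alignment score scheme
#'   (penalties positive).
#' @param K Karlin-Altschul constant.
#' @param minLength,maxEvalue acceptance filters.
#' @return one-row data.frame (`snp_id`, `chrom`, `position`,
#'   `aln_length`, `identities`, `evalue`, `score`, `pass`, `flag`) or
#'   `NULL` when there is no acceptable hit.
#' @export
mapFlank <- function(query, target, match = 1, mismatch = -2,
                     gapOpen = 5, gapExtend = 2, K = 0.621,
                     minLength = 90L, maxEvalue = 1e-40) {
  if (!length(target)) stop("empty target assembly")
  qseq <- Biostrings::DNAString(query$seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  alns <- lapply(seq_along(target), function(i)
    Biostrings::pairwiseAlignment(
      qseq, target[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = gapOpen, gapExtension = gapExtend))
  scores <- vapply(alns, Biostrings::score, 0)
  best <- which.max(scores)
  if (sum(abs(scores - scores[best]) < 1e-9) > 1L) return(NULL)  # ambiguous
  aln <- alns[[best]]
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  alnLen <- nchar(pat)
  ident <- Biostrings::nmatch(aln)
  ntot <- sum(as.numeric(Biostrings::width(target)))
  evalue <- K * nchar(query$seq) * ntot *
    exp(-.kaLambda(match, mismatch) * Biostrings::score(aln))
  ## walk alignment columns to transfer the query centre
  qpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  spos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  centre <- query$center_offset
  mapped <- NA_integer_; flag <- "center_unaligned"
  pc <- strsplit(pat, "")[[1L]]; sc <- strsplit(sub, "")[[1L]]
  for (col in seq_len(alnLen)) {
    if (pc[col] != "-") qpos <- qpos + 1L
    if (sc[col] != "-") spos <- spos + 1L
    if (pc[col] != "-" && qpos == centre) {
      if (sc[col] == "-") { flag <- "center_deleted" }
      else { mapped <- spos; flag <- "ok" }
      break
    }
  }
  pass <- (alnLen > minLength) && (evalue < maxEvalue) && flag == "ok"
  if (is.na(mapped) && flag != "center_deleted") return(NULL)
  data.frame(snp_id = query$snp_id, chrom = names(target)[best],
             position = mapped, aln_length = alnLen, identities = ident,
             evalue = evalue, score = Biostrings::score(aln),
             pass = pass, flag = flag, stringsAsFactors = FALSE)
}

#' Map a table of flank queries
#'
#' @param queries data.frame from [extractFlanks()].
#' @param target DNAStringSet of the target assembly.
#' @param ... passed to [mapFlank()].
#' @return data.frame of mapped loci (queries with no acceptable hit are
#'   omitted).
#' @export
mapFlanks <- function(queries, target, ...) {
  rows <- lapply(seq_len(nrow(queries)), function(i)
    mapFlank(queries[i, ], target, ...))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(snp_id = character(), chrom = character(),
                      position = integer(), aln_length = integer(),
                      identities = integer(), evalue = numeric(),
                      score = numeric(), pass = logical(),
                      flag = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Are two loci co-located on the target assembly?
#'
#' @param chromA,posA,chromB,posB chromosome and position of each locus.
#' @param window co-location window in bp (default 100,000, inclusive).
#' @return logical.
#' @export
lociColocated <- function(chromA, posA, chromB, posB, window = 1e5) {
  chromA == chromB & abs(posA - posB) <= window
}

#' Read a 12-column tabular alignment file
#'
#' Adapter for externally produced alignment tables (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score).  The acceptance
#' filters (alignment length > 90, e-value < 1e-40) are applied as a
#' `pass` column.
#'
#' @param path tab-separated file without header.
#' @param minLength,maxEvalue acceptance filters.
#' @return data.frame with named columns and a `pass` flag.
#' @export
readAlignmentTable <- function(path, minLength = 90L, maxEvalue = 1e-40) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) stop("expected 12 columns, found ", ncol(tab))
  names(tab) <- c("query", "subject", "identity", "length", "mismatches",
                  "gap_opens", "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bitscore")
  tab$pass <- tab$length > minLength & tab$evalue < maxEvalue
  tab
}
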