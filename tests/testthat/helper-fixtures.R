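## Shared fixtures: small genotype builders and scaled-down cohort configs.

## Build a GenotypeData from a lines x SNPs dosage matrix.
makeGeno <- function(D, chrom = NULL, pos = NULL, depth = NULL,
                     ecotype = NULL) {
  D <- as.matrix(D)
  dimnames(D) <- NULL
  m <- ncol(D)
  if (is.null(chrom)) chrom <- rep("A01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = rep("A", m), alt = rep("T", m))
  names(gr) <- paste0("S", chrom, "_", pos)
  li <- data.frame(line_id = sprintf("L%03d", seq_len(nrow(D))))
  if (!is.null(ecotype)) li$ecotype <- ecotype
  GenotypeData(t(D), gr, li, depth = if (!is.null(depth)) t(depth))
}

## Scaled cohort: the study's structure (90 lines, 47/43 ecotypes, default
## divergence, depth, missingness, LD targets) on a four-chromosome genome,
## keeping simulation cost small.
scaledConfig <- function(seed = 1L, qtl = TRUE, ...) {
  SimulationConfig(
    chromosomes = data.frame(name = c("A01", "A02", "C01", "C02"),
                             length = c(8e6, 8e6, 1e7, 1e7)),
    qtlSpec = if (qtl) data.frame(chrom = "A01", pos = 4e6, effect = 2.0)
              else data.frame(chrom = character(), pos = numeric(),
                              effect = numeric()),
    seed = seed, ...)
}

noQtl <- data.frame(chrom = character(), pos = numeric(), effect = numeric())

## r2 between two dosage columns of an (unfiltered) panel
pairR2 <- function(geno, id1, id2) {
  d <- t(dosages(geno))
  suppressWarnings(stats::cor(d[, id1], d[, id2],
                              use = "pairwise.complete.obs"))^2
}
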