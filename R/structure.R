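#' @include AllClasses.R
NULL

## dosage matrix as lines x SNPs with per-SNP alt-allele frequency,
## mean-imputed; monomorphic sites dropped
.standardizedDosage <- function(geno, scale = c("none", "unit")) {
  scale <- match.arg(scale)
  d <- if (is(geno, "GenotypeData")) t(dosages(geno)) else as.matrix(geno)
  if (nrow(d) < 2L) stop("at least 2 lines required")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  mu <- 2 * p
  for (j in which(colSums(is.na(d)) > 0))
    d[is.na(d[, j]), j] <- mu[j]
  z <- sweep(d, 2L, mu)
  if (scale == "unit")
    z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  list(z = z, p = p)
}

#' Variance-standardized genetic relationship matrix
#'
#' Missing dosages are mean-imputed per site, each site's dosage column is
#' centred by `2p` and scaled by `sqrt(2p(1-p))`, and the relationship
#' matrix is the scaled matrix times its transpose divided by the number of
#' (polymorphic) sites.  Monomorphic sites are skipped.
#'
#' @param geno a [GenotypeData] or lines x SNPs dosage matrix.
#' @return symmetric line x line matrix.
#' @export
grmVarianceStandardized <- function(geno) {
  s <- .standardizedDosage(geno, "unit")
  g <- tcrossprod(s$z) / ncol(s$z)
  dimnames(g) <- list(rownames(s$z), rownames(s$z))
  g
}

#' Centered-IBS kinship matrix
#'
#' Dosage columns are centred by `2p` (no variance scaling) and the kinship
#' is the centred cross-product normalized by `2 * sum(p * (1 - p))`.
#' Missing dosages are mean-imputed.  Positive semidefinite by
#' construction; used as the polygenic covariance in the mixed model
#' (any positive scale factor is absorbed by the variance component).
#'
#' @inheritParams grmVarianceStandardized
#' @return symmetric line x line kinship matrix.
#' @export
kinshipCenteredIBS <- function(geno) {
  s <- .standardizedDosage(geno, "none")
  k <- tcrossprod(s$z) / (2 * sum(s$p * (1 - s$p)))
  dimnames(k) <- list(rownames(s$z), rownames(s$z))
  k
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of the (variance-standardized) relationship matrix;
#' coordinates are eigenvectors scaled by the square root of their
#' (non-negative-clipped) eigenvalues, percent variance is
#' `eigenvalue / trace * 100`.  Sign convention: in each component the
#' largest-magnitude loading is positive.
#'
#' @param grm symmetric relationship matrix, e.g. from
#'   [grmVarianceStandardized()].
#' @param k number of components to keep (default 10, capped at the matrix
#'   dimension).
#' @return A [PCAResult-class].
#' @export
pcaGRM <- function(grm, k = 10L) {
  grm <- as.matrix(grm)
  if (any(!is.finite(grm))) stop("non-finite entries in relationship matrix")
  e <- eigen(grm, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  k <- min(as.integer(k), ncol(grm))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- sweep(vec, 2L, sqrt(lam[seq_len(k)]), "*")
  rownames(coords) <- rownames(grm)
  colnames(coords) <- paste0("PC", seq_len(k))
  new("PCAResult", coords = coords,
      percentVar = lam / sum(lam) * 100)
}
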