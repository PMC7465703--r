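#' @include AllClasses.R
NULL

#' Pairwise r-squared within distance frames
#'
#' For every same-chromosome SNP pair within `frame` bp, the squared
#' Pearson correlation of dosage vectors over lines non-missing at both
#' sites.  Pairs with fewer than `minN` complete lines or zero variance at
#' either site are skipped (counted in the `skipped` attribute).
#'
#' @param geno a [GenotypeData] (positions sorted per chromosome).
#' @param frame maximum pair distance in bp (default 1,500,000).
#' @param minN minimum complete lines per pair.
#' @return data.frame with `chrom`, `snp_i`, `snp_j`, `dist`, `r2`, `n`;
#'   attribute `skipped` counts excluded pairs.
#' @export
pairwiseR2 <- function(geno, frame = 1.5e6, minN = 10L) {
  stopifnot(is(geno, "GenotypeData"))
  rr <- rowRanges(geno)
  chrom <- as.character(seqnames(rr))
  out <- vector("list", 0L)
  skipped <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- start(rr)[idx]
    o <- order(pos)
    idx <- idx[o]; pos <- pos[o]
    D <- t(dosages(geno)[idx, , drop = FALSE])  # lines x SNPs
    M <- !is.na(D)
    D0 <- D; D0[!M] <- 0
    storage.mode(M) <- "double"
    D0sq <- D0^2
    ns <- length(pos)
    res <- vector("list", ns)
    for (j in seq_len(ns - 1L)) {
      hi <- j
      while (hi < ns && pos[hi + 1L] - pos[j] <= frame) hi <- hi + 1L
      if (hi == j) next
      cols <- (j + 1L):hi
      x <- D0[, j]; mx <- M[, j]
      nn <- drop(crossprod(mx, M[, cols, drop = FALSE]))
      Sx <- drop(crossprod(x, M[, cols, drop = FALSE]))
      Sy <- drop(crossprod(mx, D0[, cols, drop = FALSE]))
      Sxy <- drop(crossprod(x, D0[, cols, drop = FALSE]))
      Sxx <- drop(crossprod(x^2, M[, cols, drop = FALSE]))
      Syy <- drop(crossprod(mx, D0sq[, cols, drop = FALSE]))
      vx <- nn * Sxx - Sx^2
      vy <- nn * Syy - Sy^2
      ok <- nn >= minN & vx > 0 & vy > 0
      skipped <- skipped + sum(!ok)
      if (!any(ok)) next
      r2 <- (nn[ok] * Sxy[ok] - Sx[ok] * Sy[ok])^2 / (vx[ok] * vy[ok])
      res[[j]] <- data.frame(
        chrom = ch, snp_i = rownames(dosages(geno))[idx[j]],
        snp_j = rownames(dosages(geno))[idx[cols[ok]]],
        dist = pos[cols[ok]] - pos[j], r2 = pmin(r2, 1),
        n = as.integer(nn[ok]), stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(pairs))
    pairs <- data.frame(chrom = character(), snp_i = character(),
                        snp_j = character(), dist = numeric(),
                        r2 = numeric(), n = integer())
  rownames(pairs) <- NULL
  attr(pairs, "skipped") <- skipped
  attr(pairs, "frame") <- frame
  pairs
}

#' Proportion of high-LD pairs per distance bin
#'
#' Bins are half-open `[k*bin, (k+1)*bin)`; the proportion is the fraction
#' of pairs in the bin with `r2 > thr` (strict).  Empty bins are emitted
#' with `NA` proportion.
#'
#' @param pairs pair table from [pairwiseR2()].
#' @param bin bin width in bp (default 30,000).
#' @param thr r-squared threshold (default 0.25).
#' @param frame upper distance limit; defaults to the pair table's frame.
#' @return data.frame with `bin_start`, `bin_end`, `n_pairs`, `proportion`.
#' @export
binProportions <- function(pairs, bin = 3e4, thr = 0.25, frame = NULL) {
  if (!nrow(pairs)) stop("empty pair table")
  if (is.null(frame)) frame <- attr(pairs, "frame") %||% max(pairs$dist)
  nb <- ceiling(frame / bin)
  k <- pmin(floor(pairs$dist / bin), nb - 1L)
  np <- tabulate(k + 1L, nbins = nb)
  nhigh <- tabulate((k + 1L)[pairs$r2 > thr], nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1L) * bin,
             bin_end = seq_len(nb) * bin,
             n_pairs = np,
             proportion = ifelse(np > 0L, nhigh / np, NA_real_))
}

## first distance at which the loess curve falls to thr; bisection between
## grid points.  NULL if degenerate.
.crossingPoint <- function(fit, from, to, thr, ngrid = 256L) {
  grid <- seq(from, to, length.out = ngrid)
  f <- stats::predict(fit, data.frame(dist = grid))
  ok <- !is.na(f)
  if (!any(ok)) return(list(x = NA_real_, flag = "fit_failed"))
  grid <- grid[ok]; f <- f[ok]
  if (f[1L] <= thr) return(list(x = 0, flag = "below_threshold_at_origin"))
  below <- which(f <= thr)
  if (!length(below)) return(list(x = NA_real_, flag = "no_crossing"))
  i <- below[1L]
  lo <- grid[i - 1L]; hi <- grid[i]
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    fm <- stats::predict(fit, data.frame(dist = mid))
    if (is.na(fm)) break
    if (isTRUE(fm > thr)) lo <- mid else hi <- mid
    if (hi - lo < 1) break
  }
  list(x = (lo + hi) / 2, flag = "ok")
}

#' LD decay length at a threshold, with bootstrap SE
#'
#' Fits a local-regression curve of r-squared on distance (loess, span 0.5,
#' degree 2) and reports the smallest distance at which the fitted curve
#' falls to `thr`, located by bisection between evaluation points.  The SE
#' is the standard deviation of the statistic over `nBoot` pair-level
#' bootstrap resamples.  A curve that starts below the threshold is flagged
#' `below_threshold_at_origin` (length 0); one that never reaches it within
#' the frame is flagged `no_crossing` (length `NA`).
#'
#' @param pairs pair table from [pairwiseR2()] (>= 500 pairs unless
#'   `minPairs` is lowered).
#' @param thr r-squared threshold (default 0.25).
#' @param nBoot bootstrap resamples (0 skips the SE).
#' @param seed seed for the bootstrap resampling.
#' @param span,degree loess parameters.
#' @param minPairs minimum pair count.
#' @param maxPairs pair tables larger than this are subsampled (without
#'   replacement, deterministic under `seed`) before fitting, to bound the
#'   smoothing cost.
#' @return list with `length`, `se`, `flag`, `curve` (data.frame of the
#'   fitted curve), `n_pairs`.
#' @export
decayLength <- function(pairs, thr = 0.25, nBoot = 100L, seed = 1L,
                        span = 0.5, degree = 2, minPairs = 500L,
                        maxPairs = 100000L) {
  if (nrow(pairs) < minPairs)
    stop("too few pairs (", nrow(pairs), ") for decay estimation")
  set.seed(seed)
  if (nrow(pairs) > maxPairs)
    pairs <- pairs[sample.int(nrow(pairs), maxPairs), ]
  fit <- stats::loess(r2 ~ dist, data = pairs, span = span, degree = degree,
                      surface = "interpolate",
                      control = stats::loess.control(trace.hat = "approximate"))
  lim <- range(pairs$dist)
  cr <- .crossingPoint(fit, lim[1L], lim[2L], thr)
  grid <- seq(lim[1L], lim[2L], length.out = 200L)
  curve <- data.frame(dist = grid,
                      r2 = stats::predict(fit, data.frame(dist = grid)))
  se <- NA_real_
  if (nBoot > 0L && cr$flag == "ok") {
    bl <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
      bi <- sample.int(nrow(pairs), replace = TRUE)
      bf <- try(stats::loess(r2 ~ dist, data = pairs[bi, ], span = span,
                             degree = degree, surface = "interpolate",
                             control = stats::loess.control(
                               trace.hat = "approximate")), silent = TRUE)
      if (inherits(bf, "try-error")) next
      bc <- .crossingPoint(bf, lim[1L], lim[2L], thr, ngrid = 128L)
      if (bc$flag == "ok") bl[b] <- bc$x
    }
    se <- stats::sd(bl, na.rm = TRUE)
  }
  list(length = cr$x, se = se, flag = cr$flag, curve = curve,
       n_pairs = nrow(pairs))
}

#' Per-subgenome LD decay summary
#'
#' Computes pairwise r-squared, then the smoothed decay curve, block length
#' at the threshold (with bootstrap SE) and 30-kb bin proportions for three
#' scopes: subgenome A, subgenome C, and the whole genome.
#'
#' @param geno a [GenotypeData].
#' @param frame pair distance frame in bp.
#' @param bin bin width for [binProportions()].
#' @param thr r-squared threshold.
#' @param nBoot bootstrap resamples for the SE.
#' @param seed bootstrap seed.
#' @param minN minimum complete lines per pair.
#' @return An [LDDecaySummary-class].
#' @export
summarizeLD <- function(geno, frame = 1.5e6, bin = 3e4, thr = 0.25,
                        nBoot = 100L, seed = 1L, minN = 10L) {
  pairs <- pairwiseR2(geno, frame = frame, minN = minN)
  sub <- substr(pairs$chrom, 1L, 1L)
  scopes <- list(A = pairs[sub == "A", ], C = pairs[sub == "C", ],
                 genome = pairs)
  scopes <- scopes[vapply(scopes, nrow, 0L) > 0L]
  out <- lapply(names(scopes), function(nm) {
    pp <- scopes[[nm]]
    dl <- decayLength(pp, thr = thr, nBoot = nBoot, seed = seed)
    dl$bins <- binProportions(pp, bin = bin, thr = thr, frame = frame)
    dl
  })
  new("LDDecaySummary", scopes = stats::setNames(out, names(scopes)),
      params = c(frame = frame, bin = bin, threshold = thr))
}
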