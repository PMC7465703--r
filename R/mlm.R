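#' @include AllClasses.R
NULL

## Profiled REML log-likelihood at delta = sigma_e^2 / sigma_g^2, given the
## eigendecomposition (d) of the covariance and rotated y/X.  Returns the
## restricted log-likelihood and the profiled sigma_g^2.
.remlProfile <- function(delta, d, ystar, Xstar, ldetXtX) {
  n <- length(ystar); q <- ncol(Xstar)
  w <- d + delta
  sw <- sqrt(w)
  Xs <- Xstar / sw
  ys <- ystar / sw
  A <- crossprod(Xs)
  cb <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cb)) return(list(ll = -Inf, sigma_g2 = NA_real_))
  beta <- backsolve(cb, forwardsolve(t(cb), crossprod(Xs, ys)))
  R <- sum((ys - Xs %*% beta)^2)
  sigma_g2 <- R / (n - q)
  ldetA <- 2 * sum(log(diag(cb)))
  ll <- -0.5 * ((n - q) * log(2 * pi) + (n - q) * log(sigma_g2) +
                  sum(log(w)) + ldetA - ldetXtX + (n - q))
  list(ll = ll, sigma_g2 = sigma_g2)
}

#' REML fit of the null polygenic model
#'
#' Fits `y = X beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, using a single
#' eigendecomposition of `K`: `y` and `X` are rotated by the eigenvectors
#' and the REML log-likelihood is maximized in the one-dimensional variance
#' ratio `delta = sigma_e^2 / sigma_g^2` over a log-spaced grid followed by
#' local refinement.
#'
#' @param y phenotype vector (lines with missing phenotype are dropped,
#'   together with the matching rows of `X` and `K`).
#' @param X fixed-effect design matrix (including the intercept).
#' @param K symmetric positive-semidefinite covariance (kinship) matrix.
#' @param gridSize number of grid points for the initial delta search.
#' @param deltaRange log10 range of the delta grid.
#' @return object of class `remlFit`: a list with `sigma_g2`, `sigma_e2`,
#'   `delta`, `loglik`, `h2` (`sigma_g2 / (sigma_g2 + sigma_e2)`),
#'   `unidentifiable`/`boundary` flags, the eigendecomposition (`U`, `d`),
#'   rotated data, and `n`, `q`.
#' @export
fitNullREML <- function(y, X, K, gridSize = 64L, deltaRange = c(-5, 5)) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  K <- as.matrix(K)[keep, keep, drop = FALSE]
  n <- length(y); q <- ncol(X)
  if (nrow(X) != n || nrow(K) != n) stop("dimension mismatch")
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- setdiff(seq_len(q), qrX$pivot[seq_len(qrX$rank)])
    nm <- colnames(X)[bad] %||% paste0("column ", bad)
    stop("singular covariates: ", paste(nm, collapse = ", "))
  }
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    warning("covariance matrix has clearly negative eigenvalues")
  d <- pmax(e$values, 0)
  U <- e$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)
  ldetXtX <- as.numeric(determinant(crossprod(X))$modulus)
  grid <- 10^seq(deltaRange[1L], deltaRange[2L], length.out = gridSize)
  lls <- vapply(grid, function(dl)
    .remlProfile(dl, d, ystar, Xstar, ldetXtX)$ll, 0)
  i <- which.max(lls)
  unident <- diff(range(lls[is.finite(lls)])) < 1e-6
  boundary <- i == 1L || i == gridSize
  if (unident) {
    delta <- grid[gridSize]    # report on the grid boundary, flagged
    boundary <- TRUE
  } else if (boundary) {
    delta <- grid[i]
  } else {
    ## -Inf profile values at degenerate delta are expected; optimize warns
    opt <- suppressWarnings(stats::optimize(function(dl)
      .remlProfile(dl, d, ystar, Xstar, ldetXtX)$ll,
      lower = grid[i - 1L], upper = grid[i + 1L], maximum = TRUE,
      tol = 1e-8))
    delta <- opt$maximum
  }
  pr <- .remlProfile(delta, d, ystar, Xstar, ldetXtX)
  sigma_g2 <- pr$sigma_g2
  sigma_e2 <- delta * sigma_g2
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
                 loglik = pr$ll, h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                 unidentifiable = unident, boundary = boundary,
                 U = U, d = d, ystar = ystar, Xstar = Xstar,
                 keep = keep, n = n, q = q),
            class = "remlFit")
}

#' @export
print.remlFit <- function(x, ...) {
  cat(sprintf(
    "remlFit: n = %d, q = %d, sigma_g2 = %.4g, sigma_e2 = %.4g, logLik = %.4f%s\n",
    x$n, x$q, x$sigma_g2, x$sigma_e2, x$loglik,
    if (x$unidentifiable) " (delta unidentifiable)" else ""))
  invisible(x)
}

## kinship compression: average-linkage clustering of lines on kinship
## similarity; returns the expanded group-mean covariance and group count
.compressKinship <- function(K, ngroups) {
  n <- nrow(K)
  ngroups <- max(1L, min(n, as.integer(ngroups)))
  if (ngroups == n) return(list(C = K, groups = seq_len(n), k = n))
  dd <- stats::as.dist(max(K) - K)
  hc <- stats::hclust(dd, method = "average")
  grp <- stats::cutree(hc, k = ngroups)
  B <- matrix(0, ngroups, ngroups)
  for (g in seq_len(ngroups)) for (h in seq_len(g)) {
    B[g, h] <- B[h, g] <- mean(K[grp == g, grp == h, drop = FALSE])
  }
  C <- B[grp, grp]
  dimnames(C) <- dimnames(K)
  list(C = C, groups = grp, k = ngroups)
}

#' Genome scan with the compressed mixed linear model
#'
#' For each SNP, the (mean-imputed) marker dosage is appended to the fixed
#' effects and tested by generalized least squares with the variance
#' components of the null fit (P3D).  With compression on, lines are
#' grouped by average-linkage clustering on the kinship matrix, the kinship
#' is replaced by group means, and the group count is chosen to maximize
#' the null REML likelihood over `n / compressionGrid`.
#'
#' Monomorphic markers get `p = 1`, zero effect and a flag.
#'
#' @param y named phenotype vector for one environment (year).
#' @param X covariate matrix (intercept plus principal components); row
#'   order must match `y`.
#' @param K kinship matrix from [kinshipCenteredIBS()].
#' @param geno a [GenotypeData] with columns matching `names(y)`.
#' @param cfg an [MLMConfig].
#' @param year label stored in the result.
#' @return An [AssociationResult-class].
#' @export
scanMarkers <- function(y, X, K, geno, cfg = MLMConfig(), year = "") {
  stopifnot(is(geno, "GenotypeData"), is(cfg, "MLMConfig"))
  ids <- lineIds(geno)
  if (!is.null(names(y))) {
    stopifnot(all(names(y) %in% ids))
    geno <- geno[, names(y)]
    ids <- names(y)
  }
  y <- as.numeric(y)
  keep <- !is.na(y)
  y <- y[keep]
  X <- as.matrix(X)[keep, , drop = FALSE]
  K <- as.matrix(K)[ids, ids][keep, keep]
  D <- t(dosages(geno))[keep, , drop = FALSE]   # lines x SNPs
  n <- length(y); q <- ncol(X)

  ## compression selection by null REML likelihood
  kgrid <- if (cfg@useCompression)
    sort(unique(pmax(1L, round(n / cfg@compressionGrid))), decreasing = TRUE)
  else n
  best <- NULL; bestC <- NULL; bestk <- n
  for (kg in kgrid) {
    cp <- .compressKinship(K, kg)
    fit <- fitNullREML(y, X, cp$C)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit; bestC <- cp$C; bestk <- cp$k
    }
  }
  fit <- best

  ## P3D generalized least squares, vectorized across markers
  v <- fit$sigma_g2 * fit$d + fit$sigma_e2
  sv <- sqrt(v)
  yt <- fit$ystar / sv
  Xt <- fit$Xstar / sv
  qx <- qr(Xt)
  ry <- qr.resid(qx, yt)
  syy <- sum(ry^2)

  p_alt <- colMeans(D, na.rm = TRUE) / 2
  mono <- is.na(p_alt) | p_alt <= 0 | p_alt >= 1
  Dimp <- D
  nax <- which(colSums(is.na(D)) > 0)
  for (j in nax) Dimp[is.na(D[, j]), j] <- 2 * p_alt[j]
  Gt <- crossprod(fit$U, Dimp) / sv
  RG <- qr.resid(qx, Gt)
  den <- colSums(RG^2)
  num <- colSums(RG * ry)
  ok <- !mono & den > 1e-12
  effect <- ifelse(ok, num / den, 0)
  r2p <- ifelse(ok, num^2 / (den * syy), 0)
  r2p <- pmin(pmax(r2p, 0), 1)
  df2 <- n - q - 1L
  Fstat <- r2p / pmax(1 - r2p, .Machine$double.eps) * df2
  p <- ifelse(ok, stats::pf(Fstat, 1, df2, lower.tail = FALSE), 1)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  ## exact per-marker REML when P3D is off (slow; oracle use)
  if (!cfg@p3d) {
    for (j in which(ok)) {
      fj <- fitNullREML(y, cbind(X, marker = Dimp[, j]), bestC)
      vj <- fj$sigma_g2 * fj$d + fj$sigma_e2
      ytj <- fj$ystar / sqrt(vj)
      Xtj <- fj$Xstar / sqrt(vj)
      qj <- qr(Xtj[, -ncol(Xtj), drop = FALSE])
      rgj <- qr.resid(qj, Xtj[, ncol(Xtj)])
      ryj <- qr.resid(qj, ytj)
      r2 <- sum(rgj * ryj)^2 / (sum(rgj^2) * sum(ryj^2))
      effect[j] <- sum(rgj * ryj) / sum(rgj^2)
      Fs <- r2 / (1 - r2) * df2
      p[j] <- stats::pf(Fs, 1, df2, lower.tail = FALSE)
      r2p[j] <- r2
    }
  }

  vy <- stats::var(y)
  r2_pheno <- ifelse(ok, effect^2 * 2 * p_alt * (1 - p_alt) / vy, 0)
  rr <- rowRanges(geno)
  stats <- data.frame(
    snp_id = snpIds(geno), chrom = as.character(seqnames(rr)),
    pos = start(rr), effect = effect, p = p,
    r2_marker = r2p, r2_pheno = pmin(r2_pheno, 1),
    flag = ifelse(mono, "monomorphic", ""),
    row.names = NULL, stringsAsFactors = FALSE)
  new("AssociationResult", stats = stats,
      varComp = c(sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2),
      n = as.integer(n), year = as.character(year),
      compression = as.integer(bestk))
}

#' Per-year association scans from a phenotype table
#'
#' Convenience wrapper: computes the GRM principal components and
#' centered-IBS kinship from the genotypes, then runs [scanMarkers()] for
#' each year of the phenotype table.
#'
#' @param geno filtered [GenotypeData].
#' @param pheno phenotype data.frame (`line_id`, `year`, `gsl_umol_g`).
#' @param cfg an [MLMConfig].
#' @return named list of [AssociationResult-class], one per year.
#' @export
scanByYear <- function(geno, pheno, cfg = MLMConfig()) {
  grm <- grmVarianceStandardized(geno)
  pcs <- pcaGRM(grm, k = cfg@nPcs)@coords
  K <- kinshipCenteredIBS(geno)
  years <- sort(unique(pheno$year))
  out <- lapply(years, function(yr) {
    ph <- pheno[pheno$year == yr, ]
    y <- stats::setNames(ph$gsl_umol_g, ph$line_id)[lineIds(geno)]
    names(y) <- lineIds(geno)
    X <- cbind(intercept = 1, pcs[lineIds(geno), , drop = FALSE])
    scanMarkers(y, X, K, geno, cfg, year = yr)
  })
  stats::setNames(out, years)
}
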