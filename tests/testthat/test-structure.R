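## brute-force oracles for the relationship and kinship matrices
oracleGRM <- function(D) {
  p <- colMeans(D, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  D <- D[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(D); m <- ncol(D)
  for (j in seq_len(m)) D[is.na(D[, j]), j] <- 2 * p[j]
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (j in seq_len(m))
      s <- s + (D[i, j] - 2 * p[j]) * (D[k, j] - 2 * p[j]) /
        (2 * p[j] * (1 - p[j]))
    G[i, k] <- s / m
  }
  G
}

oracleKinship <- function(D) {
  p <- colMeans(D, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  D <- D[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(D)
  for (j in seq_along(p)) D[is.na(D[, j]), j] <- 2 * p[j]
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n))
    K[i, k] <- sum((D[i, ] - 2 * p) * (D[k, ] - 2 * p))
  K / (2 * sum(p * (1 - p)))
}

test_that("variance-standardized GRM matches the hand-computed product", {
  D <- rbind(c(0, 2), c(2, 0), c(2, 2))
  g <- grmVarianceStandardized(D)
  expect_equal(unname(g), oracleGRM(D), tolerance = 1e-12)
})

test_that("GRM of identical lines equals their self-relationship and is
          invariant to site duplication", {
  set.seed(1)
  D <- matrix(sample(0:2, 8 * 20, TRUE), 8, 20)
  D[2, ] <- D[1, ]
  g <- grmVarianceStandardized(D)
  expect_equal(g[1, 2], g[1, 1], tolerance = 1e-12)
  expect_equal(g[1, 2], g[2, 2], tolerance = 1e-12)
  g2 <- grmVarianceStandardized(cbind(D, D))
  expect_equal(g, g2, tolerance = 1e-12)
})

test_that("centered-IBS kinship matches the brute-force formula on a
          4 x 3 matrix with a missing call", {
  D <- rbind(c(0, 2, 1), c(2, 0, 0), c(2, 2, NA), c(0, 0, 2))
  K <- kinshipCenteredIBS(D)
  expect_equal(unname(K), oracleKinship(D), tolerance = 1e-12)
  expect_equal(K, t(K))
})

test_that("kinship is PSD and off-diagonals of unrelated lines centre on 0", {
  set.seed(7)
  n <- 60; m <- 800
  D <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.9), each = n)), n, m)
  K <- kinshipCenteredIBS(D)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  off <- K[upper.tri(K)]
  ## centring on sample frequencies makes rows sum to ~0, so unrelated
  ## lines centre on -mean(diag)/(n-1) rather than exactly 0
  expected <- -mean(diag(K)) / (n - 1)
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) - expected), 3 * max(se, 1 / m))
})

test_that("GRM and kinship are equivariant under line permutation", {
  set.seed(3)
  D <- matrix(sample(0:2, 10 * 50, TRUE), 10, 50)
  perm <- sample(10)
  expect_equal(unname(grmVarianceStandardized(D)[perm, perm]),
               unname(grmVarianceStandardized(D[perm, ])),
               tolerance = 1e-12)
  expect_equal(unname(kinshipCenteredIBS(D)[perm, perm]),
               unname(kinshipCenteredIBS(D[perm, ])), tolerance = 1e-12)
})

test_that("PCA percent variance matches eigenvalue/trace and sums to 100", {
  set.seed(5)
  X <- matrix(rnorm(25), 5)
  S <- crossprod(X)
  res <- pcaGRM(S, k = 5)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(res@percentVar, ev / sum(ev) * 100, tolerance = 1e-10)
  expect_equal(sum(res@percentVar), 100, tolerance = 1e-8)
})

test_that("duplicated lines get identical principal-component coordinates", {
  set.seed(9)
  D <- matrix(sample(0:2, 12 * 100, TRUE), 12, 100)
  D[5, ] <- D[4, ]
  res <- pcaGRM(grmVarianceStandardized(D))
  expect_equal(res@coords[4, ], res@coords[5, ], tolerance = 1e-8)
})

test_that("PC1 separates two diverged subpopulations", {
  ## separation sharpens with the number of independent haplotype blocks,
  ## so this one runs on the full-size default genome
  cfg <- SimulationConfig(
    nLines = 80L, nSpring = 40L, nWinter = 40L,
    fstEcotype = 0.15, qtlSpec = noQtl, seed = 12)
  sim <- simulateGenotypes(cfg)
  flt <- applyFilters(sim$genotypes)$genotypes
  res <- pcaGRM(grmVarianceStandardized(flt))
  lab <- as.integer(lineInfo(flt)$ecotype == "winter")
  r_pb <- abs(cor(res@coords[, 1], lab))
  expect_gt(r_pb, 0.9)
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(lab + 1L, dist(res@coords[, 1, drop = FALSE]))
    expect_gt(mean(sil[, "sil_width"]), 0.9)
  }
})

test_that("degenerate inputs raise informative errors", {
  expect_error(grmVarianceStandardized(matrix(2, 5, 4)), "polymorphic")
  expect_error(pcaGRM(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})
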