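## direct REML evaluation with full matrix inverses (oracle)
directREML <- function(y, X, K, sg, se) {
  n <- length(y)
  V <- sg * K + se * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - ncol(X)) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus -
                       determinant(crossprod(X))$modulus +
                       drop(t(y) %*% P %*% y)))
}

test_that("with identity covariance the scan reduces exactly to OLS and
          delta is flagged unidentifiable", {
  set.seed(42)
  n <- 40; m <- 30
  D <- matrix(sample(0:2, n * m, TRUE), n, m)
  geno <- makeGeno(D)
  y <- stats::setNames(rnorm(n), lineIds(geno))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  sc <- scanMarkers(y, matrix(1, n, 1), K, geno,
                    MLMConfig(nPcs = 0, useCompression = FALSE))
  p_ols <- sapply(seq_len(m), function(j)
    summary(lm(y ~ D[, j]))$coefficients[2, 4])
  b_ols <- sapply(seq_len(m), function(j) coef(lm(y ~ D[, j]))[2])
  expect_equal(assocStats(sc)$p, unname(p_ols), tolerance = 1e-8)
  expect_equal(assocStats(sc)$effect, unname(b_ols), tolerance = 1e-8)
  fit <- fitNullREML(y, matrix(1, n, 1), K)
  expect_true(fit$unidentifiable)
  expect_true(fit$boundary)
  expect_equal(fit$sigma_g2 + fit$sigma_e2, var(y), tolerance = 1e-6)
})

test_that("eigen-rotation REML equals the full-inverse likelihood on a
          12-line instance, and beats a dense grid search", {
  set.seed(13)
  n <- 12
  Z <- matrix(rnorm(n * 50), n)
  K <- tcrossprod(scale(Z)) / 50
  X <- cbind(1, rnorm(n))
  L <- t(chol(K + 1e-6 * diag(n)))
  y <- drop(X %*% c(1, 0.5) + sqrt(2) * L %*% rnorm(n) + rnorm(n))
  fit <- fitNullREML(y, X, K)
  expect_equal(fit$loglik, directREML(y, X, K, fit$sigma_g2, fit$sigma_e2),
               tolerance = 1e-6)
  grid <- expand.grid(sg = exp(seq(-4, 3, length.out = 80)),
                      se = exp(seq(-4, 3, length.out = 80)))
  lls <- mapply(function(a, b) directREML(y, X, K, a, b), grid$sg, grid$se)
  expect_gte(fit$loglik + 1e-6, max(lls))
})

test_that("REML recovers heritability 2/3 on average (n = 300, 50 reps)", {
  cfg <- SimulationConfig(
    nLines = 300L, nSpring = 150L, nWinter = 150L,
    chromosomes = data.frame(name = c("A01", "C01"), length = c(5e6, 5e6)),
    snpDensity = 30, qtlSpec = noQtl, seed = 99)
  sim <- simulateGenotypes(cfg)
  K <- kinshipCenteredIBS(sim$genotypes)
  n <- 300
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  X <- cbind(rep(1, n))
  set.seed(7)
  h2 <- replicate(50, {
    y <- drop(X * 10 + sqrt(2) * L %*% rnorm(n) + rnorm(n))
    f <- fitNullREML(y, X, K)
    f$sigma_g2 / (f$sigma_g2 + f$sigma_e2)
  })
  expect_lt(abs(mean(h2) - 2 / 3), 0.05)
})

test_that("compression with group count n reproduces the uncompressed scan
          exactly", {
  cfg <- scaledConfig(seed = 19)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  flt <- applyFilters(sim$genotypes)$genotypes
  grm <- grmVarianceStandardized(flt)
  pcs <- pcaGRM(grm, k = 5)@coords
  K <- kinshipCenteredIBS(flt)
  y1 <- ph[ph$year == "2015-2016", ]
  y <- stats::setNames(y1$gsl_umol_g, y1$line_id)[lineIds(flt)]
  names(y) <- lineIds(flt)
  X <- cbind(1, pcs)
  un <- scanMarkers(y, X, K, flt, MLMConfig(useCompression = FALSE))
  cp <- scanMarkers(y, X, K, flt,
                    MLMConfig(useCompression = TRUE, compressionGrid = 1))
  expect_equal(assocStats(un)$p, assocStats(cp)$p, tolerance = 1e-10)
  expect_equal(cp@compression, length(y))
})

test_that("p-values are invariant to affine rescaling of the phenotype", {
  cfg <- scaledConfig(seed = 21)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  flt <- applyFilters(sim$genotypes)$genotypes
  grm <- grmVarianceStandardized(flt)
  pcs <- pcaGRM(grm, k = 5)@coords
  K <- kinshipCenteredIBS(flt)
  y1 <- ph[ph$year == "2016-2017", ]
  y <- stats::setNames(y1$gsl_umol_g, y1$line_id)[lineIds(flt)]
  names(y) <- lineIds(flt)
  X <- cbind(1, pcs)
  cfg_m <- MLMConfig(useCompression = FALSE)
  s1 <- scanMarkers(y, X, K, flt, cfg_m)
  s2 <- scanMarkers(3 * y + 10, X, K, flt, cfg_m)
  expect_equal(assocStats(s1)$p, assocStats(s2)$p, tolerance = 1e-6)
  expect_equal(assocStats(s2)$effect, 3 * assocStats(s1)$effect,
               tolerance = 1e-6)
})

test_that("monomorphic markers are flagged with p = 1 and zero effect", {
  set.seed(2)
  D <- cbind(matrix(sample(0:2, 20 * 5, TRUE), 20, 5), rep(2, 20))
  geno <- makeGeno(D)
  y <- stats::setNames(rnorm(20), lineIds(geno))
  K <- diag(20); dimnames(K) <- list(names(y), names(y))
  sc <- scanMarkers(y, matrix(1, 20, 1), K, geno,
                    MLMConfig(nPcs = 0, useCompression = FALSE))
  st <- assocStats(sc)
  expect_equal(st$p[6], 1)
  expect_equal(st$effect[6], 0)
  expect_equal(st$flag[6], "monomorphic")
})

test_that("singular covariates raise an error naming the collinear column", {
  set.seed(4)
  n <- 20
  X <- cbind(intercept = 1, pc1 = rnorm(n))
  X <- cbind(X, dup = X[, "pc1"])
  expect_error(fitNullREML(rnorm(n), X, diag(n)), "dup")
})

test_that("marker variance explained approaches effect^2 2p(1-p)/var(y) at
          n = 500", {
  diffs <- vapply(77:79, function(s) {
    cfg <- SimulationConfig(
      nLines = 500L, nSpring = 250L, nWinter = 250L,
      chromosomes = data.frame(name = c("A01", "C01"), length = c(6e6, 6e6)),
      qtlSpec = data.frame(chrom = "A01", pos = 3e6, effect = 2.0),
      polygenicSd = 1, seed = s)
    sim <- simulateGenotypes(cfg)
    ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
    flt <- applyFilters(sim$genotypes)$genotypes
    sc <- scanByYear(flt, ph, MLMConfig())
    st <- assocStats(sc[[1]])
    cid <- sim$truth$causal$snp_id
    stopifnot(cid %in% st$snp_id)
    y1 <- ph[ph$year == "2015-2016", "gsl_umol_g"]
    d <- dosages(flt)[cid, ]
    p <- mean(d, na.rm = TRUE) / 2
    truthR2 <- 2^2 * 2 * p * (1 - p) / var(y1)
    abs(st$r2_pheno[st$snp_id == cid] - truthR2)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})
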