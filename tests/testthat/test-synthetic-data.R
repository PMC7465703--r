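test_that("same config and seed reproduce the simulation byte for byte", {
  cfg <- scaledConfig(seed = 11)
  s1 <- simulateGenotypes(cfg)
  s2 <- simulateGenotypes(cfg)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_identical(depths(s1$genotypes), depths(s2$genotypes))
  expect_identical(s1$truth$ancestral, s2$truth$ancestral)
  p1 <- simulatePhenotypes(s1$genotypes, s1$truth, cfg)
  p2 <- simulatePhenotypes(s2$genotypes, s2$truth, cfg)
  expect_identical(p1, p2)
})

test_that("default cohort composition is 47 spring and 43 winter lines", {
  cfg <- scaledConfig(seed = 3)
  sim <- simulateGenotypes(cfg)
  eco <- table(lineInfo(sim$genotypes)$ecotype)
  expect_equal(ncol(sim$genotypes), 90L)
  expect_equal(unname(eco[["spring"]]), 47L)
  expect_equal(unname(eco[["winter"]]), 43L)
  expect_true(all(c("winter_dark", "winter_yellow") %in%
                    lineInfo(sim$genotypes)$subpop))
})

test_that("dosages stay in the 0/1/2/missing domain and het is bounded", {
  cfg <- scaledConfig(seed = 5)
  sim <- simulateGenotypes(cfg)
  d <- dosages(sim$genotypes)
  expect_true(all(d[!is.na(d)] %in% 0:2))
  st <- siteStats(sim$genotypes)
  normal <- !(st$snp_id %in% sim$truth$artifact_sites)
  nobs <- (1 - st$missing_rate[normal]) * ncol(sim$genotypes)
  bound <- cfg@residualHet + 3 * sqrt(cfg@residualHet *
                                        (1 - cfg@residualHet) / pmax(nobs, 1))
  ## residual het enters on top of the block draw; allow the artifact-free
  ## sites to sit at the configured rate plus binomial noise
  expect_gt(mean(st$het_rate[normal] <= bound, na.rm = TRUE), 0.97)
  art <- st$snp_id %in% sim$truth$artifact_sites
  expect_gt(mean(st$het_rate[art] > 0.4, na.rm = TRUE), 0.6)
})

test_that("without structure or artifacts, pooled allele frequencies track
          the recorded ancestral draw", {
  cfg <- SimulationConfig(
    nLines = 500L, nSpring = 250L, nWinter = 250L,
    chromosomes = data.frame(name = c("A01", "C01"), length = c(4e6, 4e6)),
    fstEcotype = 0, fstSeedcolor = 0, artifactSiteRate = 0,
    residualHet = 0, qtlSpec = noQtl, seed = 17)
  sim <- simulateGenotypes(cfg)
  d <- dosages(sim$genotypes)
  phat <- rowMeans(d, na.rm = TRUE) / 2
  nobs <- rowSums(!is.na(d))
  p0 <- sim$truth$ancestral
  se <- sqrt(p0 * (1 - p0) / nobs)
  within3 <- abs(phat - p0) <= 3 * se
  expect_gt(mean(within3), 0.98)
})

test_that("phenotype calibration recovers the configured mean and
          between-year correlation", {
  means <- numeric(20); cors <- numeric(20)
  for (s in 1:20) {
    cfg <- SimulationConfig(
      nLines = 200L, nSpring = 100L, nWinter = 100L,
      chromosomes = data.frame(name = c("A01", "C01"), length = c(4e6, 4e6)),
      qtlSpec = data.frame(chrom = "A01", pos = 2e6, effect = 2.0),
      seed = 400 + s)
    sim <- simulateGenotypes(cfg)
    ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
    means[s] <- mean(ph$gsl_umol_g)
    cors[s] <- mean(yearCorrelations(ph)$correlations$r)
  }
  expect_lt(abs(mean(means) - 16.3), 0.5)
  expect_lt(abs(mean(cors) - 0.7), 0.1)
})

test_that("null phenotype (no QTLs, no polygenics, no ecotype effect) gives
          uniform single-marker p-values", {
  cfg <- scaledConfig(seed = 23, qtl = FALSE,
                      polygenicSd = 0, ecotypeEffect = 0)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  y1 <- ph[ph$year == "2015-2016", ]
  y <- stats::setNames(y1$gsl_umol_g, y1$line_id)[lineIds(sim$genotypes)]
  n <- length(y)
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  ## sparse SNP subset with >= 500 kb spacing: beyond the decay length, so
  ## the p-values entering the KS test are effectively independent
  rr <- rowRanges(sim$genotypes)
  keep <- unlist(lapply(split(seq_along(rr), as.character(seqnames(rr))),
                        function(i) {
    pos <- start(rr)[i]
    sel <- i[1]; last <- pos[1]
    for (k in seq_along(i)[-1]) {
      if (pos[k] - last >= 5e5) { sel <- c(sel, i[k]); last <- pos[k] }
    }
    sel
  }))
  sc <- scanMarkers(y, matrix(1, n, 1), K, sim$genotypes[sort(keep), ],
                    MLMConfig(nPcs = 0, useCompression = FALSE))
  p <- assocStats(sc)$p[assocStats(sc)$flag == ""]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("perfect year correlation with zero noise gives identical yearly
          vectors up to the year offsets", {
  cfg <- scaledConfig(seed = 31, targetYearCorrelation = 1)
  sim <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(sim$genotypes, sim$truth, cfg)
  w <- reshape(ph[, c("line_id", "year", "gsl_umol_g")], idvar = "line_id",
               timevar = "year", direction = "wide")
  v <- as.matrix(w[, -1])
  off <- sweep(v, 1L, v[, 1L])
  expect_true(all(apply(off, 2L, function(x) diff(range(x))) < 1e-9))
})

test_that("phenotype simulation rejects mismatched genotype/truth pairs", {
  cfg <- scaledConfig(seed = 41)
  sim <- simulateGenotypes(cfg)
  truth_bad <- sim$truth
  truth_bad$causal$snp_id[1] <- "SA01_999999999"
  expect_error(simulatePhenotypes(sim$genotypes, truth_bad, cfg),
               "absent")
})

test_that("config validity catches inconsistent cohorts and QTL placement", {
  expect_error(SimulationConfig(nLines = 90, nSpring = 50, nWinter = 50),
               "nSpring")
  expect_error(SimulationConfig(
    chromosomes = data.frame(name = "A01", length = 1e6),
    qtlSpec = data.frame(chrom = "A01", pos = 2e6, effect = 1)),
    "positions")
  expect_error(SimulationConfig(
    chromosomes = data.frame(name = c("A01", "A01"), length = c(1e6, 1e6))),
    "unique")
})

test_that("annotation bundle: zero edits give the identity coordinate map", {
  ann <- simulateAnnotation(seed = 5, edits = data.frame(
    chrom = character(), pos = integer(), type = character(),
    length = integer()))
  expect_identical(as.character(ann$assembly2), as.character(ann$genome))
  pos <- c(1L, 1000L, 250000L)
  expect_equal(mapThroughEdits(ann$edits, "A01", pos), as.numeric(pos))
})

test_that("a single insertion before P shifts all mapped positions >= P", {
  ed <- data.frame(chrom = "A01", pos = 50000L, type = "ins", length = 1000L)
  ann <- simulateAnnotation(seed = 6, edits = ed)
  below <- c(10L, 49999L)
  above <- c(50000L, 120000L)
  expect_equal(mapThroughEdits(ed, "A01", below), as.numeric(below))
  expect_equal(mapThroughEdits(ed, "A01", above), as.numeric(above + 1000))
  ## the edited sequence is longer by exactly the insertion
  expect_equal(Biostrings::width(ann$assembly2["A01"]),
               Biostrings::width(ann$genome["A01"]) + 1000L)
})

test_that("deletions map interior positions to NA and shift downstream", {
  ed <- data.frame(chrom = "A01", pos = 1000L, type = "del", length = 100L)
  expect_true(is.na(mapThroughEdits(ed, "A01", 1050L)))
  expect_equal(mapThroughEdits(ed, "A01", 2000L), 1900)
  expect_equal(mapThroughEdits(ed, "A01", 999L), 999)
})
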