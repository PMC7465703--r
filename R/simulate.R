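#' @include AllClasses.R
NULL

#' Default rapeseed chromosome table
#'
#' Ten A-subgenome chromosomes (~23-37 Mb) and nine C-subgenome chromosomes
#' (~38-60 Mb), mirroring the relative sizes of the two ancestral genomes.
#'
#' @return data.frame with columns `name` and `length` (bp).
#' @export
defaultChromosomes <- function() {
  a_len <- round(seq(23e6, 37e6, length.out = 10) / 1e5) * 1e5
  c_len <- round(seq(38e6, 60e6, length.out = 9) / 1e5) * 1e5
  data.frame(
    name = c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9)),
    length = c(a_len, c_len),
    stringsAsFactors = FALSE)
}

#' Simulation parameters for the synthetic GBS cohort
#'
#' The defaults emulate a 90-line inbred rapeseed panel: 47 spring and 43
#' winter lines (winter split into dark- and yellow-seeded subclusters),
#' 19 chromosomes in two subgenomes, subgenome-specific LD decay crossing
#' r-squared = 0.25 near 177 kb (A) and 265 kb (C), GBS-like missingness,
#' per-call depth around 37.3 +/- 8.7 reads, residual heterozygosity plus a
#' small fraction of artifact sites whose heterozygosity exceeds 0.4, and a
#' three-year glucosinolate phenotype (mean 16.3 umol/g) with planted QTLs
#' and a between-year correlation target of 0.7.
#'
#' @param nLines,nSpring,nWinter panel composition; `nSpring + nWinter`
#'   must equal `nLines`.
#' @param winterYellowFraction fraction of winter lines in the yellow-seeded
#'   subcluster.
#' @param chromosomes data.frame with `name` (unique, starting with the
#'   subgenome letter) and `length` in bp.
#' @param snpDensity expected SNPs per Mb after variant calling.
#' @param fstEcotype,fstSeedcolor Balding-Nichols divergence of the
#'   spring/winter split and of the winter seed-colour split.
#' @param ldTargetA,ldTargetC distance (bp) at which expected pairwise
#'   r-squared crosses 0.25 in each subgenome.
#' @param residualHet per-call probability of a heterozygous call at
#'   ordinary sites (incomplete inbreeding).
#' @param artifactSiteRate fraction of sites behaving as homeolog-collapse
#'   artifacts, with heterozygosity drawn above 0.4.
#' @param siteDiscordance per-call probability that a site disagrees with
#'   its haplotype block (recent mutation / gene conversion); keeps
#'   within-block LD just below 1.
#' @param missingRateBeta two shape parameters of the Beta distribution of
#'   per-site missing-call rates.
#' @param depthMean,depthSd negative-binomial mean and SD of per-call read
#'   depth.
#' @param qtlSpec data.frame of planted QTLs with columns `chrom`, `pos`,
#'   `effect` (umol/g per alternate-allele copy).
#' @param qtlMaf allele frequency forced at causal sites (shared across
#'   subpopulations, so the causal signal is not confounded with structure).
#' @param ecotypeEffect phenotype offset between winter and spring lines
#'   (umol/g; winter gets `+ecotypeEffect/2`, spring `-ecotypeEffect/2`).
#' @param polygenicSd SD of the kinship-correlated polygenic term (umol/g).
#' @param phenotypeMean cohort mean glucosinolate content (umol/g fresh
#'   weight).
#' @param yearEffects three additive year offsets (centred internally).
#' @param targetYearCorrelation between-year Pearson correlation of line
#'   values that the noise variance is calibrated to.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return A `SimulationConfig` object.
#' @export
SimulationConfig <- function(nLines = 90L, nSpring = 47L, nWinter = 43L,
                             winterYellowFraction = 0.3,
                             chromosomes = defaultChromosomes(),
                             snpDensity = 16.5,
                             fstEcotype = 0.15, fstSeedcolor = 0.05,
                             ldTargetA = 177000, ldTargetC = 265000,
                             residualHet = 0.05, artifactSiteRate = 0.03,
                             siteDiscordance = 0.03,
                             missingRateBeta = c(1.5, 8.5),
                             depthMean = 37.3, depthSd = 8.7,
                             qtlSpec = data.frame(chrom = "A07",
                                                  pos = 26967214,
                                                  effect = 2.0),
                             qtlMaf = 0.3,
                             ecotypeEffect = 1.5, polygenicSd = 2.5,
                             phenotypeMean = 16.3,
                             yearEffects = c(-0.8, 0.2, 0.6),
                             targetYearCorrelation = 0.7,
                             seed = 1L) {
  new("SimulationConfig",
      nLines = as.integer(nLines), nSpring = as.integer(nSpring),
      nWinter = as.integer(nWinter),
      winterYellowFraction = winterYellowFraction,
      chromosomes = chromosomes, snpDensity = snpDensity,
      fstEcotype = fstEcotype, fstSeedcolor = fstSeedcolor,
      ldTargetA = ldTargetA, ldTargetC = ldTargetC,
      residualHet = residualHet, artifactSiteRate = artifactSiteRate,
      siteDiscordance = siteDiscordance,
      missingRateBeta = missingRateBeta,
      depthMean = depthMean, depthSd = depthSd,
      qtlSpec = qtlSpec, qtlMaf = qtlMaf,
      ecotypeEffect = ecotypeEffect, polygenicSd = polygenicSd,
      phenotypeMean = phenotypeMean, yearEffects = yearEffects,
      targetYearCorrelation = targetYearCorrelation,
      seed = as.integer(seed))
}

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig", representation(
  nLines = "integer", nSpring = "integer", nWinter = "integer",
  winterYellowFraction = "numeric", chromosomes = "data.frame",
  snpDensity = "numeric", fstEcotype = "numeric", fstSeedcolor = "numeric",
  ldTargetA = "numeric", ldTargetC = "numeric",
  residualHet = "numeric", artifactSiteRate = "numeric",
  siteDiscordance = "numeric",
  missingRateBeta = "numeric", depthMean = "numeric", depthSd = "numeric",
  qtlSpec = "data.frame", qtlMaf = "numeric",
  ecotypeEffect = "numeric", polygenicSd = "numeric",
  phenotypeMean = "numeric", yearEffects = "numeric",
  targetYearCorrelation = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nLines < 1L) msg <- c(msg, "nLines must be positive")
  if (object@nSpring + object@nWinter != object@nLines)
    msg <- c(msg, "nSpring + nWinter must equal nLines")
  props <- c(object@winterYellowFraction, object@fstEcotype,
             object@fstSeedcolor, object@residualHet,
             object@artifactSiteRate, object@siteDiscordance,
             object@targetYearCorrelation)
  if (any(props < 0 | props > 1))
    msg <- c(msg, "proportions must lie in [0, 1]")
  ch <- object@chromosomes
  if (nrow(ch) < 1L) msg <- c(msg, "at least one chromosome required")
  if (anyDuplicated(ch$name)) msg <- c(msg, "chromosome names must be unique")
  if (!all(substr(ch$name, 1, 1) %in% c("A", "C")))
    msg <- c(msg, "chromosome names must start with subgenome letter A or C")
  if (any(ch$length <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  q <- object@qtlSpec
  if (nrow(q)) {
    i <- match(q$chrom, ch$name)
    if (anyNA(i))
      msg <- c(msg, "QTL chromosomes must be declared in the chromosome table")
    else if (any(q$pos < 1 | q$pos > ch$length[i]))
      msg <- c(msg, "QTL positions must lie on their chromosome")
  }
  if (length(object@missingRateBeta) != 2L || any(object@missingRateBeta <= 0))
    msg <- c(msg, "missingRateBeta must be two positive shape parameters")
  if (object@depthSd^2 <= object@depthMean)
    msg <- c(msg, "depthSd^2 must exceed depthMean (negative-binomial)")
  if (length(object@yearEffects) != 3L)
    msg <- c(msg, "yearEffects must have length 3")
  if (length(msg)) msg else TRUE
})

## Two-level Balding-Nichols draw: subpopulation frequency around p with
## divergence F (returns p itself when F == 0).
.bnDraw <- function(p, fst) {
  if (fst == 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

## One chromosome of the haplotype-block mosaic: block boundaries form a
## Poisson (Markov renewal) process of rate `rate` per bp, every site in a
## block carries the block haplotype (up to a per-site polarity flip and a
## small per-call discordance), and block-haplotype frequencies follow the
## two-level Balding-Nichols hierarchy.  `rowOf` maps lines to rows of the
## subpopulation frequency matrix (spring / winter_dark / winter_yellow).
## `forceFreq` fixes the frequency of the blocks containing the given local
## site indices (used to plant causal variants free of structure).
.simChromBlocks <- function(pos, len, rate, rowOf, fstE, fstS,
                            discordance, forceFreq = NULL) {
  nl <- length(rowOf); ns <- length(pos)
  nexp <- max(10L, ceiling(3 * len * rate) + 10L)
  bnd <- cumsum(stats::rexp(nexp, rate))
  while (length(bnd) && max(bnd) < len)
    bnd <- c(bnd, max(bnd) + cumsum(stats::rexp(nexp, rate)))
  bnd <- bnd[bnd < len]
  block <- findInterval(pos, bnd) + 1L
  nb <- max(block)
  q0 <- stats::runif(nb, 0.05, 0.95)
  qs <- .bnDraw(q0, fstE); qw <- .bnDraw(q0, fstE)
  qmat <- rbind(spring = qs,
                winter_dark = .bnDraw(qw, fstS),
                winter_yellow = .bnDraw(qw, fstS))
  flip <- stats::runif(ns) < 0.5
  if (!is.null(forceFreq)) {
    for (k in seq_len(nrow(forceFreq))) {
      b <- block[forceFreq$site[k]]
      q0[b] <- forceFreq$freq[k]
      qmat[, b] <- forceFreq$freq[k]
      flip[forceFreq$site[k]] <- FALSE
    }
  }
  Ql <- qmat[rowOf, , drop = FALSE]                  # lines x blocks
  H <- matrix(stats::runif(nl * nb), nl, nb) < Ql    # block haplotypes
  X <- H[, block, drop = FALSE]
  if (any(flip)) X[, flip] <- !X[, flip]
  if (discordance > 0) {
    Pl <- Ql[, block, drop = FALSE]
    if (any(flip)) Pl[, flip] <- 1 - Pl[, flip]
    mask <- matrix(stats::runif(nl * ns) < discordance, nl, ns)
    X[mask] <- stats::runif(sum(mask)) < Pl[mask]
  }
  p0 <- ifelse(flip, 1 - q0[block], q0[block])
  psub <- qmat[, block, drop = FALSE]
  psub[, flip] <- 1 - psub[, flip]
  list(G = 2L * (X + 0L), p0 = p0, psub = psub, block = block)
}

## memo cache for pilot calibrations (deterministic: fixed internal seed)
.calCache <- new.env(parent = emptyenv())

## Pilot-based calibration of the block-boundary rate: simulate short
## chromosomes under the candidate rate with the panel's actual structure
## and noise, measure the decay length with the same estimator the LD
## module uses (loess span 0.5, degree 2, crossing at `thr`), and correct
## the rate multiplicatively (decay is exponential in the rate, so this
## converges in a couple of steps).  The pilot runs on its own fixed RNG
## substream, so the calibrated rate is a deterministic function of the
## structural parameters and does not perturb the panel's random draw.
.calibrateBlockRate <- function(target, rowOf, fstE, fstS, discordance,
                                residualHet, missBeta = c(1.5, 8.5),
                                thr = 0.25, nIter = 3L,
                                nRep = 6L, nSnp = 450L, frame = 1.5e6) {
  key <- paste(target, paste(tabulate(rowOf, 3L), collapse = "/"),
               fstE, fstS, discordance, residualHet,
               paste(missBeta, collapse = "/"), thr, sep = "|")
  if (!is.null(.calCache[[key]])) return(.calCache[[key]])
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(20260L + round(target / 1e3))
  rate <- log(0.85 / thr) / target
  nl <- length(rowOf)
  ## long pilot chromosome: keeps the pair-distance density within the
  ## frame close to the near-uniform density of real-scale chromosomes
  span <- 3 * frame
  for (it in seq_len(nIter)) {
    dists <- numeric(0); r2s <- numeric(0)
    for (rep in seq_len(nRep)) {
      pos <- sort(stats::runif(nSnp, 1, span))
      sim <- .simChromBlocks(pos, span, rate, rowOf, fstE, fstS, discordance)
      G <- sim$G
      ## emulate the measurement conditions: residual heterozygosity,
      ## GBS missingness, and the standard site filters
      if (residualHet > 0) {
        het <- matrix(stats::runif(length(G)) < residualHet, nl, nSnp)
        G[het] <- 1L
      }
      mr <- stats::rbeta(nSnp, missBeta[1L], missBeta[2L])
      miss <- matrix(stats::runif(nl * nSnp), nl, nSnp) <=
        matrix(mr, nl, nSnp, byrow = TRUE)
      G[miss] <- NA_integer_
      p <- colMeans(G, na.rm = TRUE) / 2
      hetr <- colMeans(G == 1L, na.rm = TRUE)
      keep <- !is.na(p) & pmin(p, 1 - p) > 0.03 & hetr <= 0.4 &
        colMeans(is.na(G)) <= 0.3
      if (sum(keep) < 10L) next
      cc <- suppressWarnings(
        stats::cor(G[, keep], use = "pairwise.complete.obs")^2)
      pk <- pos[keep]
      dd <- abs(outer(pk, pk, "-"))
      ut <- upper.tri(dd)
      sel <- dd[ut] <= frame & dd[ut] > 0 & !is.na(cc[ut])
      dists <- c(dists, dd[ut][sel]); r2s <- c(r2s, cc[ut][sel])
    }
    if (length(dists) < 200L) break
    ## resample to a uniform pair-distance density (the estimator is
    ## applied to real-scale chromosomes whose within-frame pair density
    ## is nearly flat, and span-0.5 loess is sensitive to it), then locate
    ## the crossing with the decay-length estimator itself
    bin <- findInterval(dists, seq(0, frame, length.out = 16L),
                        all.inside = TRUE)
    percap <- min(5000L, min(tabulate(bin, 15L)))
    sel <- unlist(lapply(1:15, function(b) {
      i <- which(bin == b)
      i[sample.int(length(i), min(percap, length(i)))]
    }))
    fit <- stats::loess(r2 ~ dist,
                        data = data.frame(dist = dists[sel], r2 = r2s[sel]),
                        span = 0.5, degree = 2, surface = "interpolate",
                        control = stats::loess.control(
                          trace.hat = "approximate"))
    cr <- .crossingPoint(fit, min(dists[sel]), max(dists[sel]), thr)
    if (cr$flag != "ok" || !is.finite(cr$x) || cr$x <= 0) break
    rate <- rate * min(2, max(0.5, cr$x / target))
  }
  .calCache[[key]] <- rate
  rate
}

## colSds without a matrixStats dependency
.colSds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  sqrt(pmax(0, colMeans(m^2) - mu^2) * n / (n - 1))
}

#' Simulate a structured GBS genotype panel
#'
#' Allele frequencies follow a two-level Balding-Nichols hierarchy (a
#' spring/winter ecotype split with divergence `fstEcotype`, then a
#' dark/yellow seed-colour split within winter with `fstSeedcolor`).
#' Haplotypes follow a Markov renewal block mosaic along each chromosome:
#' block boundaries are a Poisson process whose per-bp rate is calibrated
#' by an internal pilot simulation so that expected pairwise r-squared
#' crosses 0.25 near the configured subgenome target; sites within a block
#' share the block haplotype up to a per-site polarity and a small per-call
#' discordance.  Lines are inbred with residual heterozygosity; a small
#' fraction of artifact sites (homeolog collapse) carries heterozygosity
#' above 0.4.  Per-call depth is negative-binomial and calls are dropped
#' at a per-site Beta missing rate.
#'
#' Causal sites named in `qtlSpec` are inserted at their exact positions;
#' their haplotype block is fixed at allele frequency `qtlMaf` in every
#' subpopulation.
#'
#' @param config a [SimulationConfig].
#' @return list with elements `genotypes` (a [GenotypeData]) and `truth`
#'   (list: `causal` data.frame, `subpop`/`ecotype` labels, `ancestral`
#'   per-site allele frequencies, `subpop_freq` matrix, `polygenic`
#'   standardized polygenic values, `block_rate` and `decay_target` per
#'   subgenome, `artifact_sites`).
#' @export
#' @examples
#' cfg <- SimulationConfig(chromosomes = data.frame(name = c("A01", "C01"),
#'                                                  length = c(2e6, 2e6)),
#'                         qtlSpec = data.frame(chrom = "A01", pos = 1e6,
#'                                              effect = 2),
#'                         seed = 7)
#' sim <- simulateGenotypes(cfg)
#' sim$genotypes
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  nl <- config@nLines
  ## subpopulation labels
  nyellow <- round(config@nWinter * config@winterYellowFraction)
  subpop <- c(rep("spring", config@nSpring),
              rep("winter_dark", config@nWinter - nyellow),
              rep("winter_yellow", nyellow))
  ecotype <- ifelse(subpop == "spring", "spring", "winter")
  line_id <- sprintf("L%03d", seq_len(nl))
  rowOf <- match(subpop, c("spring", "winter_dark", "winter_yellow"))

  ch <- config@chromosomes
  ch$sub <- substr(ch$name, 1, 1)

  ## per-chromosome SNP positions, with causal sites inserted exactly
  pos_list <- lapply(seq_len(nrow(ch)), function(i) {
    n <- max(2L, round(ch$length[i] * config@snpDensity / 1e6))
    sort(sample.int(ch$length[i], n))
  })
  qtl <- config@qtlSpec
  if (nrow(qtl)) qtl$pos <- as.integer(qtl$pos)
  for (k in seq_len(nrow(qtl))) {
    i <- match(qtl$chrom[k], ch$name)
    p <- pos_list[[i]]
    if (!qtl$pos[k] %in% p) pos_list[[i]] <- sort(c(p, qtl$pos[k]))
  }

  chrom <- rep(ch$name, lengths(pos_list))
  pos <- unlist(pos_list, use.names = FALSE)
  ns <- length(pos)
  snp_id <- paste0("S", chrom, "_", pos)
  causal_idx <- match(paste0("S", qtl$chrom, "_", qtl$pos), snp_id)

  ## calibrate subgenome block rates under the panel's own structure
  rate <- c(A = NA_real_, C = NA_real_)
  target <- c(A = config@ldTargetA, C = config@ldTargetC)
  for (sg in c("A", "C")) {
    if (sg %in% ch$sub)
      rate[[sg]] <- .calibrateBlockRate(target[[sg]], rowOf,
                                        config@fstEcotype,
                                        config@fstSeedcolor,
                                        config@siteDiscordance,
                                        config@residualHet,
                                        config@missingRateBeta)
  }

  ## block-mosaic haplotypes per chromosome
  G <- matrix(0L, nl, ns)
  p0 <- numeric(ns)
  psub <- matrix(0, 3, ns,
                 dimnames = list(c("spring", "winter_dark", "winter_yellow"),
                                 snp_id))
  off <- 0L
  for (i in seq_len(nrow(ch))) {
    idx <- off + seq_along(pos_list[[i]])
    force <- NULL
    if (length(causal_idx)) {
      local <- causal_idx[causal_idx %in% idx] - off
      if (length(local))
        force <- data.frame(site = local, freq = config@qtlMaf)
    }
    sim <- .simChromBlocks(pos_list[[i]], ch$length[i], rate[[ch$sub[i]]],
                           rowOf, config@fstEcotype, config@fstSeedcolor,
                           config@siteDiscordance, forceFreq = force)
    G[, idx] <- sim$G
    p0[idx] <- sim$p0
    psub[, idx] <- sim$psub
    off <- off + length(pos_list[[i]])
  }

  ## residual heterozygosity and artifact sites
  if (config@residualHet > 0) {
    het <- matrix(stats::runif(length(G)) < config@residualHet, nl, ns)
    G[het] <- 1L
  }
  n_art <- round(config@artifactSiteRate * ns)
  art_idx <- integer(0)
  if (n_art > 0) {
    eligible <- setdiff(seq_len(ns), causal_idx)
    art_idx <- sort(sample(eligible, min(n_art, length(eligible))))
    hprob <- stats::runif(length(art_idx), 0.55, 0.9)
    for (k in seq_along(art_idx)) {
      hmask <- stats::runif(nl) < hprob[k]
      G[hmask, art_idx[k]] <- 1L
    }
  }

  ## depth and missingness
  size <- config@depthMean^2 / (config@depthSd^2 - config@depthMean)
  DP <- matrix(stats::rnbinom(length(G), mu = config@depthMean, size = size),
               nl, ns)
  miss_rate <- stats::rbeta(ns, config@missingRateBeta[1L],
                            config@missingRateBeta[2L])
  ## a planted QTL emulates a discoverable (QC-passing) locus
  if (length(causal_idx))
    miss_rate[causal_idx] <- pmin(miss_rate[causal_idx], 0.2)
  miss <- matrix(stats::runif(length(G)), nl, ns) <=
    matrix(miss_rate, nl, ns, byrow = TRUE)
  G[miss] <- NA_integer_
  DP[miss] <- 0L

  ## ref/alt alleles
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  gr <- GRanges(chrom, IRanges(pos, width = 1L), ref = ref, alt = unname(alt))
  names(gr) <- snp_id
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(ch$length, ch$name)

  li <- DataFrame(line_id = line_id, ecotype = ecotype, subpop = subpop)
  geno <- GenotypeData(t(G), gr, li, depth = t(DP))

  ## standardized polygenic values, drawn now so genotype/phenotype pairing
  ## is fixed by the genotype seed
  K <- kinshipCenteredIBS(geno)
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  u0 <- as.numeric(L %*% stats::rnorm(nl))
  sdu <- stats::sd(u0)
  if (sdu > 0) u0 <- u0 / sdu

  truth <- list(
    causal = if (nrow(qtl)) data.frame(snp_id = snp_id[causal_idx],
                                       chrom = qtl$chrom, pos = qtl$pos,
                                       effect = qtl$effect,
                                       stringsAsFactors = FALSE)
             else data.frame(snp_id = character(), chrom = character(),
                             pos = numeric(), effect = numeric()),
    subpop = stats::setNames(subpop, line_id),
    ecotype = stats::setNames(ecotype, line_id),
    ancestral = stats::setNames(p0, snp_id),
    subpop_freq = psub,
    polygenic = stats::setNames(u0, line_id),
    block_rate = rate,
    decay_target = target,
    artifact_sites = snp_id[art_idx])
  stopifnot(all(truth$causal$snp_id %in% snp_id))
  list(genotypes = geno, truth = truth)
}

#' Simulate the three-year glucosinolate phenotype
#'
#' Per line and year:
#' `value = mean + ecotype effect + sum(effect_q * dosage_q) +
#'  polygenic + year offset + noise`.
#' QTL and ecotype contributions are centred so the realized cohort mean
#' tracks `phenotypeMean`; year offsets are centred to sum to zero.  The
#' noise variance is calibrated from the realized variance of the stable
#' line value so that the expected between-year correlation equals
#' `targetYearCorrelation` (noise variance `var(L) * (1 - r) / r`).
#'
#' @param geno [GenotypeData] from [simulateGenotypes()].
#' @param truth matching truth record.
#' @param config the same [SimulationConfig].
#' @return data.frame with columns `line_id`, `ecotype`, `year`,
#'   `gsl_umol_g` (one row per line per year).
#' @export
simulatePhenotypes <- function(geno, truth, config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed + 104729L)   # distinct stream from the genotype draw
  nl <- ncol(geno)
  ids <- lineIds(geno)
  if (!identical(names(truth$polygenic), ids))
    stop("genotypes and truth are not from the same simulation")
  qtl <- truth$causal
  qsum <- numeric(nl)
  for (k in seq_len(nrow(qtl))) {
    if (!qtl$snp_id[k] %in% snpIds(geno))
      stop("QTL ", qtl$snp_id[k], " absent from genotype matrix")
    d <- dosages(geno)[qtl$snp_id[k], ]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    qsum <- qsum + qtl$effect[k] * (d - 2 * config@qtlMaf)  # centred
  }
  eco <- ifelse(truth$ecotype == "winter", 0.5, -0.5) * config@ecotypeEffect
  eco <- eco - mean(eco)
  L <- config@phenotypeMean + eco + qsum +
    config@polygenicSd * truth$polygenic
  r <- config@targetYearCorrelation
  vL <- stats::var(L)
  sigma_e <- if (r >= 1 || vL == 0) 0 else sqrt(vL * (1 - r) / r)
  yr_off <- config@yearEffects - mean(config@yearEffects)
  years <- c("2015-2016", "2016-2017", "2018-2019")
  out <- do.call(rbind, lapply(1:3, function(y) {
    val <- L + yr_off[y] + stats::rnorm(nl, 0, sigma_e)
    data.frame(line_id = ids, ecotype = as.character(truth$ecotype),
               year = years[y], gsl_umol_g = val, stringsAsFactors = FALSE)
  }))
  if (any(out$gsl_umol_g <= 0)) {
    warning("clipping non-positive simulated glucosinolate values to 0.1")
    out$gsl_umol_g <- pmax(out$gsl_umol_g, 0.1)
  }
  rownames(out) <- NULL
  out
}
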