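---
title: "Methods: mixed-model association mapping of glucosinolate content in rapeseed GBS panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model association mapping of glucosinolate content in rapeseed GBS panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

BnaGWAS implements the post-variant-calling analysis of a
genotyping-by-sequencing (GBS) panel of inbred *Brassica napus* lines
phenotyped for seed glucosinolate content over three growing seasons.
Rapeseed is an amphidiploid: its A subgenome (from *B. rapa*) and C
subgenome (from *B. oleracea*) are highly homologous, so short-read
misalignment between homeologous regions inflates apparent heterozygosity
— the motivation for the strict per-site heterozygosity filter and for
reporting linkage disequilibrium (LD) separately per subgenome.

The analysis chain is:

1. **Site filtering** (`applyFilters`). Genotype calls supported by fewer
   than 10 reads are masked to missing; then sites are removed at
   missingness > 0.30, heterozygosity > 0.40, and minor allele frequency
   (MAF) not strictly above 0.03.  The inequalities are taken literally:
   MAF strictly `>`, heterozygosity and missingness inclusive `<=`.  The
   criteria are applied in a fixed order (depth, missingness,
   heterozygosity, MAF) and each removal is attributed to the first
   criterion that fails, so the `FilterReport` is reproducible; sites that
   fail missingness only *because* of the depth mask are attributed to the
   depth criterion.  Setting `mafMin = 0` disables the MAF criterion
   (otherwise the strict inequality would still drop monomorphic sites).
   The whole operation is idempotent.

2. **Population structure** (`grmVarianceStandardized`, `pcaGRM`,
   `kinshipCenteredIBS`).  The relationship matrix centres each dosage
   column by `2p` and scales by `sqrt(2p(1-p))`; principal components are
   its eigenvectors scaled by the square roots of the eigenvalues.  The
   centered-IBS kinship uses centring without variance scaling,
   normalized by `2*sum(p(1-p))`.  Because the mixed model estimates a
   genetic variance component, the kinship is only defined up to a
   positive scale factor — any such factor is absorbed by `sigma_g^2` and
   leaves p-values unchanged.  Missing dosages are mean-imputed per site
   for both matrices; a pairwise-complete alternative was rejected
   because it does not guarantee positive semidefiniteness.

3. **Per-year mixed-model scan** (`fitNullREML`, `scanMarkers`).  The
   model is `y = X beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
   `e ~ N(0, sigma_e^2 I)`; `X` holds the intercept and the first five
   principal components.  REML uses a single eigendecomposition of `K`:
   after rotating `y` and `X` by the eigenvectors the restricted
   likelihood is one-dimensional in `delta = sigma_e^2/sigma_g^2` and is
   maximized over a log-spaced grid (`10^-5` to `10^5`, 64 points)
   followed by Brent refinement.  When the likelihood is flat in `delta`
   (e.g. `K = I`) the fit is flagged `unidentifiable` and reported on the
   grid boundary; the total variance is still correct.  Marker tests use
   P3D: variance components are fixed at their null estimates and each
   (mean-imputed) marker is tested by generalized least squares with an
   F-test.  With compression on, lines are grouped by average-linkage
   clustering on kinship similarity, the kinship is replaced by group
   means, and the group count is chosen from `n/{1,2,4,8}` by the null
   REML likelihood; group count `n` reproduces the uncompressed scan
   exactly.  Exact per-marker REML is available behind `p3d = FALSE` for
   cross-checks.

   Two per-marker variance-explained quantities are reported, because the
   field uses both: `r2_marker`, the squared partial correlation of the
   marker with the rotated phenotype given the covariates (a
   model-conditional quantity), and `r2_pheno`, the share of *total*
   phenotypic variance, `effect^2 * 2p(1-p) / var(y)` — the quantity
   usually quoted as "percent of phenotypic variation explained".  They
   differ whenever the kinship absorbs substantial background variance.

4. **Cross-year combination** (`irwinHallPdf`, `irwinHallCdf`,
   `combineYears`).  Under the null, each year's p-value is Uniform(0,1),
   so the sum of the three is Irwin–Hall distributed with `n = 3`.  The
   combined significance of a SNP is the Irwin–Hall CDF at the observed
   sum.  The density at the sum is computed and reported alongside, but a
   density is not a probability: only the CDF can be compared coherently
   to a Bonferroni-corrected alpha, and on the left tail (small sums) the
   two order SNPs identically.  Both the Bonferroni flag
   (`alpha/m`, printed to two significant figures) and the soft flag
   (combined p < 5e-4) are set on the CDF.

5. **LD decay** (`pairwiseR2`, `binProportions`, `decayLength`,
   `summarizeLD`).  r² is the squared Pearson correlation of dosage
   vectors over lines non-missing at both sites, for same-chromosome
   pairs within a 1,500 kb frame (pairs with fewer than 10 complete lines
   or zero variance are skipped and counted).  For inbred lines the
   dosage correlation coincides asymptotically with the haplotype r², so
   no EM phasing is attempted.  The decay curve is a loess fit (span 0.5,
   degree 2) of r² on distance; the block length is the first distance at
   which the fitted curve falls to 0.25, refined by bisection, with a
   pair-level bootstrap SE (default B = 100).  Curves that start below
   the threshold are flagged `below_threshold_at_origin` (length 0);
   curves that never reach it, `no_crossing`.  Bin proportions use
   half-open 30 kb bins and a strict `r² > 0.25`.  The frame is applied
   per chromosome: pairs on different chromosomes have no defined
   distance.

6. **Annotation windows** (`genesInWindow`, `classifyEffect`).  Candidate
   genes are those whose span intersects ±100 kb around a significant
   SNP; the distance is signed (negative upstream of the gene start) and
   0 inside the gene, and hits sort by absolute distance.  The effect
   classifier is deliberately minimal: intergenic / intronic /
   synonymous / missense, with stop gain or loss, start loss and broken
   CDS lengths folded into `other`.  Codons are resolved strand- and
   phase-aware from the CDS segments and translated with the standard
   genetic code (`no.init.codon = TRUE`, so a mutated start codon is not
   silently re-translated as methionine).

7. **Cross-assembly mapping** (`extractFlanks`, `mapFlank`,
   `lociColocated`).  A 101-base query (50 bp either side of the SNP) is
   aligned locally to the target assembly with match +1, mismatch −2, gap
   open −5, gap extend −2; the e-value uses the ungapped Karlin–Altschul
   formula with `lambda` solved numerically for that scheme and
   `K = 0.621` (the standard constant for +1/−2 nucleotide scoring).  A
   hit is accepted iff alignment length > 90 *and* e-value < 1e-40, both
   strict; the SNP position is transferred through the alignment column
   holding the query centre.  Ties in best score are rejected as
   ambiguous — detected at target-sequence granularity, since co-optimal
   alignments within one sequence are not enumerable through the aligner.
   `readAlignmentTable` accepts externally produced 12-column tabular
   alignments for real-genome use, applying the same acceptance filters.
   Loci co-location uses an inclusive 100 kb window.

## The synthetic cohort

No public genotype matrix accompanies the study conditions at desk scale,
so the package carries a first-class generator
(`simulateGenotypes`, `simulatePhenotypes`, `simulateAnnotation`) whose
defaults *are* the cohort the analysis assumes:

* 90 inbred lines — 47 spring, 43 winter, the winter lines split into
  dark- and yellow-seeded subclusters (30/13 at the default yellow
  fraction 0.3);
* 19 chromosomes — A01–A10 at 23–37 Mb, C01–C09 at 38–60 Mb — with
  ~16.5 SNPs/Mb, giving ≈12.2k SNPs genome-wide;
* allele frequencies from a two-level Balding–Nichols hierarchy
  (ecotype divergence 0.15, seed-colour divergence 0.05);
* haplotypes from a Markov renewal block mosaic: block boundaries form a
  Poisson process along the chromosome, all sites in a block carry the
  block haplotype up to a per-site polarity and a 3% per-call
  discordance.  The boundary rate per subgenome is calibrated by an
  internal pilot simulation so that the measured r² decay crosses 0.25
  near 177 kb (A) and 265 kb (C).  The pilot emulates the full
  measurement path — residual heterozygosity, missingness,
  pairwise-complete r², the standard site filters, and the same loess
  estimator on density-uniform pairs — because the span-0.5 smoother is
  sensitive to the pair-distance density.  The pilot runs on a fixed
  internal RNG substream, so the calibrated rate is a deterministic
  function of the structural parameters and leaves the panel's own
  random draw untouched;
* GBS-like noise: per-call depth from a negative binomial with mean 37.3
  and SD 8.7; per-site missing rates from Beta(1.5, 8.5) (≈15% mean);
  5% residual heterozygosity; 3% artifact sites whose heterozygosity is
  drawn in (0.55, 0.9), emulating homeolog collapse — these are the
  sites the 0.40 heterozygosity filter exists to remove;
* a three-year phenotype `mean + ecotype + QTL + polygenic + year +
  noise` with cohort mean 16.3 µmol/g, ecotype offset 1.5 µmol/g,
  polygenic SD 2.5 µmol/g (covariance proportional to the realized
  kinship), and noise variance calibrated so the expected between-year
  correlation is 0.7 (the printed range of the study is 0.67–0.79).
  QTL and ecotype contributions are centred so the realized mean tracks
  the target; year offsets are centred to sum to zero.  One value per
  line per year is emitted — the assay pooled seeds of three plants per
  plot, so no within-line replicate structure exists to simulate.

The default planted QTL sits at A07:26,967,214 with an additive effect of
2.0 µmol/g per allele copy and frequency 0.3 in every subpopulation —
planting it frequency-neutral across subpopulations keeps the causal
signal unconfounded with structure.  Its haplotype block is pinned to
that frequency, and its per-site missing rate is capped at 0.2: a planted
QTL emulates a *discoverable* locus, i.e. one that passes genotyping QC,
as any reported association site by definition did.

What the generator does **not** emulate: restriction-site biology and
read-level artefacts (the pipeline starts at the genotype matrix),
linkage between the artifact process and local homeology, selection or
pedigree structure within subpopulations, multi-allelic sites, and any
worldwide reference panel.  Passing tests therefore demonstrate that the
statistics behave correctly under the stated generative assumptions, not
that the biology of any real panel is captured.

`simulateAnnotation` emits a sequence-bearing miniature companion —
toy chromosomes (default 2 × 300 kb), two-exon gene models, SNPs at
configurable offsets, and a second assembly derived by a recorded edit
list — because emitting the ~740 Mb of the full coordinate system as text
is not sensible.  Window annotation at full scale needs coordinates only
and uses `simulateGeneModels`; sequence-level operations (effect
classification, flank mapping) run on the miniature bundle.

## Numerical choices and degenerate inputs

* REML grid `10^-5..10^5`; flat likelihoods flagged rather than silently
  resolved; collinear covariates are an error naming the column.
* Monomorphic markers: p = 1, effect 0, flagged — never dropped, so SNP
  sets stay aligned across years for the combination step.
* Irwin–Hall closed forms use the alternating-sum formula directly; at
  `n = 3` the terms are small and no special stabilization is needed
  (verified against a 10⁷-draw Monte Carlo and by quadrature).
* Loess crossing located by bisection to < 1 bp between grid points;
  pair tables larger than 100k rows are subsampled deterministically
  before smoothing to bound the O(n) loess cost.
* `decayLength` SEs come from a pair-level nonparametric bootstrap
  (B = 100 by default); the resampling seed is explicit.
* The local aligner's ambiguity rule rejects tied best scores instead of
  picking arbitrarily; a query centre falling in a deletion maps to
  nothing (`center_deleted`).

## Scaled problem sizes used by the test suite

The calibration tests run at sizes chosen to make their Monte-Carlo error
small relative to the tolerances while keeping the suite fast: type-I
error and planted-QTL recovery use 20 cohorts of 90 lines on a
four-chromosome (36 Mb) genome; REML recovery uses one 300-line cohort
and 50 phenotype replicates; LD recovery uses 10 cohorts on six 12 Mb
chromosomes (the decay contract needs many haplotype blocks per
subgenome); the PCA separation check runs on the full 19-chromosome
genome because eigenvector separation sharpens with the number of
independent blocks.  `scripts/acceptance.R` runs the full default-scale
cohort (~12.2k SNPs).

## Known limitations

* The combined Irwin–Hall p-value assumes the three yearly p-values are
  independent under the null; year-to-year phenotype correlation of 0.7
  makes them positively dependent, so combined tails are anticonservative
  — visible in the soft-threshold counts on the synthetic cohort.  The
  same caveat applies to any use of this combination on real data; the
  per-year type-I error is calibrated, the combined one is a ranking
  device with a conventional threshold.
* The compression group-count grid `n/{1,2,4,8}` is a pragmatic default;
  the optimum is data-dependent.
* `r2_marker` vs `r2_pheno`: which of the two a given external tool
  reports varies; both are emitted so results can be compared either way.
* The pipeline's `runPipeline`/`PipelineConfig` orchestration (plus the
  thin Rscript wrapper in `inst/scripts/run_pipeline.R`) is the
  command-line surface of the package; there is deliberately no
  workflow-engine dependency.
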