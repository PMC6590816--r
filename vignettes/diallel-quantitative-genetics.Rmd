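---
title: "Additive-dominance genetic analysis of half-diallel progeny trials"
author: "diallelqg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive-dominance genetic analysis of half-diallel progeny trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelqg)
```

## The problem

Tree breeding programs cross a set of elite parents in an incomplete
half-diallel and plant the full-sib offspring in randomized complete blocks
with small (typically 5-tree) plots. Two questions drive the analysis of
such trials:

1. How much of the phenotypic variation in growth and wood-quality traits is
   additive (usable by recurrent selection of parents) versus dominance
   (usable only by deploying specific crosses or clones)?
2. Do genome-wide markers — co-dominant SNPs or dominant presence/absence
   markers from reduced-representation sequencing — recover the same genetic
   parameters and parent/offspring rankings as the pedigree, and how many
   markers are enough?

`diallelqg` implements the full chain: pedigree and genomic relationship
matrices, REML estimation of the individual-tree mixed model, heritability
and genetic-correlation re-parameterizations, marker-subsampling stability
analysis, and near-infrared (NIR) calibration of wood traits so that
expensive wet-lab phenotypes can be predicted for the bulk of the
population. A synthetic half-diallel generator produces populations with
the exact statistical structure the estimators assume, so every stage is
testable end to end without field data.

## The model

The single-trait individual-tree mixed model is

$$ y = X\beta + Z_p p + Z_a a + Z_d d + e $$

with block fixed effects $\beta$, iid plot effects
$p \sim N(0, I\sigma^2_p)$, additive genetic effects
$a \sim N(0, K_a \sigma^2_a)$, dominance effects
$d \sim N(0, K_d \sigma^2_d)$ and residuals $e \sim N(0, I\sigma^2_e)$.
The kernels $K_a, K_d$ are either pedigree-expected (the numerator
relationship matrix $A$ and the dominance matrix $D$) or marker-realized:

* SNP additive (VanRaden): $G_A = WW' / 2\sum_i p_i(1-p_i)$, $W = M - 2p$,
  genotypes coded 0/1/2;
* dominant-marker additive: $G_A = SS' / \sum_i p_i(1-p_i)$, $S = Z - p$
  with $p$ the presence frequency of each 0/1 marker (as this construction
  is conventionally printed it carries no factor 2 in the denominator; the
  scale difference rescales variance components but cancels in every matrix
  correlation and heritability ratio);
* dominance, Vitezica parameterization: genotype codes
  $\{-2p^2,\,2pq,\,-2q^2\}$, denominator $\sum_i (2p_iq_i)^2$ — orthogonal
  to the additive contrast at Hardy–Weinberg loci;
* dominance, Su parameterization: heterozygosity indicator centered on
  $2pq$, denominator $\sum_i 2p_iq_i(1-2p_iq_i)$.

Allele frequencies are always computed in-sample, which makes the grand
mean of both additive constructions exactly zero (a centering identity the
tests assert to machine precision). Missing genotypes are imputed at the
locus mean before centering, preserving that identity. No blending of $G$
toward $A$ is applied; if a kernel is numerically singular inside REML a
$10^{-8}$ diagonal jitter is used at solve time only.

Variance components are estimated by average-information (AI) REML. The AI
matrix of a variance-component model whose kernels are nearly collinear
(here: $A$-like, $D$-like and $I$) can be close to singular far from the
optimum, so the optimizer takes one expectation–maximization (EM) warm-up
step, then AI steps with a Levenberg-style diagonal ridge escalated until
the proposed step increases the restricted likelihood, with step-halving,
and a monotone EM step as the final fallback. Variances are clamped at
$10^{-10}\,\mathrm{var}(y)$; estimates at that bound are reported as 0 with
a boundary flag. Convergence requires the likelihood change below
$10^{-8}$ and the largest relative parameter change below $10^{-6}$
(default cap 200 iterations, full trajectory retained). BLUPs are
$\hat u_k = \hat\sigma^2_k K_k Z_k' P y$ at the optimum, verified against a
dense solve of Henderson's equations in the tests.

Heritabilities use the plot variance in the denominator:
$h^2_N = \sigma^2_a / (\sigma^2_p + \sigma^2_a + \sigma^2_d + \sigma^2_e)$
and $h^2_B$ adds $\sigma^2_d$ to the numerator. Because the two share one
denominator, $(h^2_B - h^2_N)/h^2_N = \sigma^2_d/\sigma^2_a$ exactly —
a useful internal-consistency check for published heritability tables.
Standard errors of any transform of the components come from the delta
method on the inverse AI matrix; this is our choice, since published
reports rarely state how their "approximate SEs" were obtained.

The two-trait additive model stacks both traits with additive covariance
$\begin{pmatrix}\sigma^2_{a_i} & \sigma_{a_{ij}}\\ \sigma_{a_{ij}} &
\sigma^2_{a_j}\end{pmatrix} \otimes K_a$ and an analogous $2\times 2$
residual structure (no dominance term). When no plot effects are requested
the fit rotates both trait vectors by the eigenvectors of $K_a$; the
covariance then decomposes into $2\times2$ blocks
$\lambda_i B + R$ per eigenvalue, making each restricted-likelihood
evaluation $O(n)$. $B$ and $R$ are parameterized by their Cholesky factors
(always positive semidefinite, so no projection step is ever needed) and
maximized with L-BFGS-B; the observed-information matrix at the optimum
supplies delta-method SEs for the genetic correlation
$r = \sigma_{a_{ij}} / \sigma_{a_i}\sigma_{a_j}$. With plot effects the
same Cholesky parameterization is optimized over the dense likelihood.

## The synthetic population

`simulate_diallel_population()` generates, by default, the trial layout the
estimators target: 46 unrelated parents, 45 distinct unordered parent
pairs, 22 offspring per family trimmed evenly to 970 trees, 5 randomized
complete blocks with 5-tree family plots nested in blocks (the field layout
rarely states whether plots are nested or crossed; we nest, and the model
indexes one plot effect per block-by-plot combination). Founder genotypes
are drawn at Hardy–Weinberg proportions with allele frequencies uniform on
[0.05, 0.5] at 30,000 unlinked biallelic loci; offspring are produced by
Mendelian gamete sampling. Dominant presence/absence markers are derived as
carrier indicators (1 if genotype ≥ 1), with optional iid dropout.

Phenotypes follow the fitted model generatively. A trait is built from
`n_qtl` causal loci sampled among the genotyped SNPs — 1,000 by default,
reflecting the highly polygenic architecture of growth and wood-property
traits. Additive values are centered allele counts times normal effects;
dominance deviations use the orthogonal heterozygosity coding. Both are
rescaled empirically (divide by the realized SD, multiply by the target SD)
so the in-sample variances equal the targets exactly, which makes
parameter-recovery experiments sharp; plot effects and residuals are drawn,
not rescaled. The default variance architecture is
$\sigma^2_a = 0.23$, $\sigma^2_d = 0.207$ (dominance-to-additive ratio
0.9), $\sigma^2_p = 0.05$, $\sigma^2_e = 0.513$ on a unit total — the
narrow-sense 0.23 / broad-sense 0.44 regime typical of diameter growth in
hybrid eucalypt trials; the 5% plot share is a realistic small-plot value
chosen once.

Two things the generator deliberately does **not** emulate: linkage (loci
are unlinked, so realized relationships at 30K markers have only
$\sim0.004$ SD of within-family Mendelian dispersion, versus a few percent
for real genomes with a finite number of chromosomes) and pedigree errors.
Consequently a passing parameter-recovery test says the estimator is
unbiased and correctly weighted under its own assumptions — it does not say
the additive/dominance separation is as precise as in real linked genomes.
Indeed, at this design the restricted likelihood frequently peaks at a
boundary (dominance 0, or additive near 0) in individual replicates; across
replicates the estimates are unbiased (replicate means within a few
hundredths of truth) but single-replicate deviations of 0.1–0.2 in
$h^2_N$ occur. That dispersion is a property of REML at 45 families with
effectively pedigree-level relationship information, and it matches the
magnitude of the AI-based standard errors the package itself reports.

NIR spectra are simulated on the standard grid — 700 wavelengths from
1,100 nm in 2 nm steps (every second wavelength of a 1 nm instrument grid;
we fix the *count* at 700, so the grid ends at 2,498 nm) — as a fixed
smooth baseline plus smooth Gaussian-band loadings weighted by per-sample
concentrations, the first of which are standardized trait values, plus iid
noise. Spectra are therefore linearly informative about the traits, which
is exactly the assumption behind linear calibration; instrument
nonlinearities and scatter are represented only through the preprocessing
menu, not generated.

## NIR calibration

Calibration mirrors standard chemometric practice: Kennard–Stone max-min
selection (deterministic; ties broken toward the earliest sample) picks a
representative subset among wet-lab-measured samples (350, or 200 for
traits measured on fewer samples); a seeded random split forms estimation
and validation sets (250/100 or 150/50); for each preprocessing in
\{none, SNV, first and second Savitzky–Golay derivatives (window 15, order
2), MSC\} the number of PLS components is chosen by 10-fold
cross-validation with a one-standard-error rule toward parsimony, and the
model is scored on the held-out set by RMSEP, bias and $R^2_p$. A
calibration is accepted when $R^2_p \ge 0.60$ — a threshold that
generalizes the conventional judgment that a 0.60 model is still usable
while a 0.36 one is not — and only accepted models may predict the
unmeasured remainder of the population (an explicit `force` flag overrides
the gate). PLS is the classical orthogonal-scores PLS1, one trait at a
time; at full rank its predictions coincide with ordinary least squares,
which the tests exploit as an oracle alongside an independent PLS
implementation.

## Numerical and design choices

* **Dominant-marker MAF.** Only an "estimated MAF" filter is conventionally
  reported for presence/absence markers; we estimate the allele frequency
  under HWE as $p = 1 - \sqrt{1-f}$ from the presence frequency $f$ and
  filter on $\min(p, 1-p) \ge 0.02$ (call rate $\ge 0.80$). SNPs are
  filtered at call rate $\ge 0.90$ and MAF $\ge 0.01$.
* **Pedigree conventions.** Founders are unrelated and non-inbred;
  dominance diagonals use the non-inbred convention $d_{ii}=1$ (the target
  populations are F1/F2/backcross from unrelated parents, so inbreeding
  adjustments are out of scope). Pedigrees are topologically sorted
  internally; input order is free; cycles are reported with the offending
  path.
* **Marker subsampling.** Subsets are drawn uniformly without replacement,
  10 replicates per size by default (published stability analyses rarely
  state their replicate count). Relationship histograms default to 0.05-wide
  bins on [-0.4, 1.6], extended as needed so counts always total
  $n(n-1)/2$.
* **Individuals phenotyped for a subset of traits** are dropped from the
  model rows for that trait while kernels keep full dimension (pure
  subsetting; marker-only individuals add nothing to a single-trait fit).
* **Problem sizes in the tests.** Unit tests run on a shared 970-tree
  population with 4,000 loci; the end-to-end checks use the full 30,000
  loci and 5 replicates for parameter recovery (the acceptance script uses
  10). These sizes were fixed as the package's standard verification
  workload.
* **Correlation tables.** Pearson p-values use the exact t transform and
  are reported unadjusted, as is conventional for trait-correlation tables;
  a Benjamini–Hochberg column is emitted alongside for readers who want it.
  Spearman correlations compare breeding-value rankings across kernel
  sources.

## Worked example

```{r example, eval = FALSE}
pop <- simulate_diallel_population(n_loci = 30000, seed = 11)
GA <- build_GA_snp(pop$genotypes)
GD <- build_GD_vitezica(pop$genotypes)
fit <- fit_univariate_ad(mixed_model_spec(pop$phenotypes, "y", GA, GD))
heritabilities(fit)
#> hN2 = 0.300 +/- 0.101   hB2 = 0.494 +/- 0.117   s2_d/s2_a = 0.65
```

(Printed from an actual run; the generator's truth is $h^2_N = 0.23$,
$h^2_B = 0.437$, and the deviations here are within the reported SEs —
see the dispersion discussion above.)

The configuration-driven runner `run_pipeline()` chains every stage —
simulation or file input, filtering, all six kernel constructions,
univariate and bivariate fits, heritability/correlation/stability reports,
NIR calibration — with per-stage logging, provenance-stamped outputs and a
JSON manifest; a failed trait-by-kernel fit is logged and skipped rather
than aborting the run.

## Known limitations

* No linkage, selection, inbreeding across generations, or coalescent
  realism in the generator; no LD pruning or chromosome-stratified GRMs.
* No inbreeding-adjusted dominance matrices.
* The bivariate model omits dominance (as is standard for genetic
  correlations) and, with plot effects, falls back to a dense likelihood
  that is practical only for moderate n.
* No spatial or genotype-by-environment terms.
* NIR preprocessing is limited to the menu above; wavelength selection is
  out of scope.
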