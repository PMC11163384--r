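---
title: "Multi-population genomic prediction with local genetic correlations: models and methods"
author: "lgcblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-population genomic prediction with local genetic correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breeding programmes often need genomic prediction in several populations
at once. Pooling the populations into one reference assumes the trait is
the same trait everywhere — measured the same way and free of
genotype-by-environment interaction. Treating the performances in the two
populations as **two correlated traits** drops both assumptions: a
bivariate GBLUP borrows information across populations exactly to the
extent that their additive effects correlate. `lgcblup` goes one step
further: because the between-population correlation varies along the
genome (some regions agree strongly, some disagree, most carry little
shared signal), it partitions the genome into approximately independent
LD blocks, estimates a **local genetic correlation (LGC)** per block, and
lets groups of blocks carry their own covariance structure in the
prediction model.

## Model

For SNP $j$ with pooled counted-allele frequency $p_j$, the centered
genotype is $w_{ij} = m_{ij} - 2p_j$ and the VanRaden GRM is
$G = WW'/\sum_j 2p_j(1-p_j)$. Missing genotypes surviving QC are
mean-imputed ($w_{ij}=0$), which keeps the centering exact. Frequencies
and QC statistics are always computed on the pooled two-population
sample: the model uses a single $G$ across both populations, so the
centering must match it. A region-restricted GRM uses the denominator of
its own SNP set, so every kernel is a standalone VanRaden matrix and its
fitted $2\times2$ covariance matrix $M_k$ is interpretable as that genome
part's genetic covariance.

With disjoint populations each individual carries one record for one
trait; stacking records gives

$$V(\theta)=\sum_k \begin{bmatrix}
\sigma^2_{a_1,k} & \sigma_{a_{12},k}\\
\sigma_{a_{12},k} & \sigma^2_{a_2,k}\end{bmatrix}\!\otimes G_k
\;+\;\mathrm{diag}(\sigma^2_{e_1},\sigma^2_{e_2})\otimes I ,$$

restricted to observed records. Fixed effects are the per-trait overall
means only — the package targets pre-corrected phenotypes or de-regressed
proofs, where all systematic effects have already been removed (an
intercept-free variant exists for fully centered toy examples). The
residual covariance between populations is structurally zero: no
individual is measured in both.

## REML estimation

`fitREML()` maximizes the restricted likelihood
$-\tfrac12[\log|V|+\log|X'V^{-1}X|+y'Py]-\tfrac{n-p}{2}\log 2\pi$
(the constant is included so values are comparable across
implementations). The optimizer is average-information (AI) REML with
EM-REML warm-up (3 iterations by default), with these numerical choices:

* **Transformed parameter space.** Steps are taken in log-variances and
  the Fisher-z transform of each kernel's correlation; the gradient and
  AI matrix are mapped through the Jacobian. Every point of this space
  lies inside the positive-semidefinite cone, so no step can produce an
  invalid covariance matrix and no clamping cycle can stall the
  iteration. This matters in practice: variance components frequently hit
  boundaries (a kernel with no signal, a correlation estimated at
  $\pm 1$), and a natural-scale iteration with projection zigzags there.
* **Monotonicity.** Every proposed step — AI, Levenberg-damped AI, or the
  EM fallback — passes a line search that only accepts a non-decreasing
  restricted likelihood; step-halving otherwise. The reported trajectory
  is therefore monotone by construction.
* **Convergence** is declared when the likelihood gain falls below `tol`
  ($10^{-8}$ by default) and one probing EM step cannot improve it
  further, or when three consecutive accepted steps are below `tol`
  (a boundary optimum). Reported correlations are clamped to
  $|r| \le 0.999$.
* **Initialization** splits each population's phenotypic variance equally
  between genetic and residual parts, the genetic part equally across
  kernels, covariances at zero.

Standard errors of $h^2_p$ and $r_{g,k}$ come from the inverse AI matrix
by the delta method. The zero-covariance test refits with
$\sigma_{a_{12},k}=0$ (the parameter is simply dropped) and refers
$2(\ell_{full}-\ell_0)$, clamped at zero, to $\chi^2_1$; since the null
value is interior to the parameter space the usual calibration applies,
which the test suite confirms by simulation. If the unconstrained fit
ends below the constrained one (a sign of a difficult surface), it is
restarted from the constrained optimum before the comparison.

## LD-block partitioning

`partitionGenome()` splits each chromosome recursively: while any block
exceeds `maxBlockSnps`, the largest block is split at the admissible
breakpoint (both halves at least `minSnps` SNPs, default 25) minimizing
the summed $r^2$ between the `window` SNPs (default 50) on either side of
the break; ties go to the leftmost minimum. Squared genotype correlation
is used — phasing is out of scope. The windowed score keeps each
candidate $O(\text{window}^2)$ and reflects that a good breakpoint is one
with little *local* LD across it. Block definitions can also be supplied
externally as a TSV and bypass the splitter entirely.

## Local genetic correlations and region classes

`estimateLGC()` fits, for every block, the bivariate one-kernel model
with the block-restricted GRM — an exact per-block REML estimator of the
local correlation, with a likelihood-ratio p-value. Every block is
analyzed regardless of its univariate signal. Blocks whose fit fails or
whose local genetic variance is at the boundary yield an undefined
estimate and fall into the default class (NON or RES) — a conservative
choice that keeps the class partition exhaustive.

Two classification schemes mirror the two partitioned models:
`classifyModel1()` ranks blocks by the p-value and declares the `topK`
smallest SIG (boundary ties resolved by genomic order, earliest block
wins); `classifyModel2()` declares $\hat r_{lgc} \ge t$ POS and
$\hat r_{lgc} \le -t$ NEG with the inclusive threshold $t$ (0.5 by
default, 0.6 the common alternative). Point estimates are used as they
stand; no shrinkage is applied.

## Prediction and evaluation

`gblupSolve()` computes fixed effects by GLS and breeding values by the
conditional-expectation form
$\hat a_k = (M_k\otimes G_k)[{\rm pred},{\rm obs}]\,V^{-1}(y-X\hat b)$;
a Henderson mixed-model-equations path is provided as an independent
cross-check (the two agree to $10^{-8}$ on full-rank kernels). Validation
individuals are present in the GRMs — genomic relationships are known for
unphenotyped animals — but never contribute records; per-kernel
components sum exactly to the total GEBV.

`runCV()` performs repeated k-fold cross-validation (10×10 by default),
stratified by population so no fold loses a population; identical folds
are used by every model, making comparisons paired. Variance components —
and by default the LGC classification — are re-estimated on each training
split, so no validation phenotype can influence any training-side
quantity; `refitClasses = FALSE` instead fixes the classification once on
the full data, which is cheaper and matches the common practice of
estimating local correlations once per dataset, at the cost of a mild
optimism in the classification step. Accuracy is the validation
correlation $r(y, \widehat{GEBV})$ and unbiasedness the regression slope
of $y$ on the GEBV, computed on the validation predictions pooled per
repeat (stabler than per-fold metrics with small folds; a per-fold mode
exists).

## The synthetic-data generator

`simulateGenotypes()` draws haplotypes from a Gaussian-copula chain: a
latent AR(1) process with coefficient $\rho$ inside each block, restarted
at block boundaries, thresholded at the allele-frequency quantile. This
preserves marginal frequencies exactly, gives monotone control of
within-block LD, and guarantees zero LD across block boundaries — the
property the partitioning and kernel-separation machinery needs to be
testable with known truth. It does not emulate recombination gradients,
demographic history, selection or pedigree structure; a passing test
shows the machinery works where blocks are real, not that any particular
organism's genome has such blocks.

`simulateEffectsAndPhenotypes()` draws causal effects per block from a
bivariate normal with the block's configured correlation and rescales
each block's genic contribution so its realized variance equals the
block's share of the population's genetic variance (phenotypic variance
1, heritabilities exact by construction up to residual sampling).
Residuals are independent across populations, matching the diagonal
residual structure of the model.

Three presets define the study conditions:

* `homogeneous-<r>` — every block at correlation $r$, equal shares;
  global and local correlations coincide.
* `heterogeneous` — 2 chromosomes × 5 blocks × 60 SNPs at $n=200$ per
  population; per chromosome one block at $+0.9$, one at $-0.9$, three at
  0, with the positive blocks carrying four times the per-block variance.
  The proportions (20% positive, 20% negative, 60% null) produce
  mixed-sign local structure while the variance weighting integrates to a
  *positive* global correlation ($\approx +0.34$) — the situation
  observed in real two-population datasets, where global correlations are
  positive yet individual regions disagree in sign. With equal shares the
  global correlation would cancel to zero, which no reported trait shows.
  Ten blocks (rather than many more) keep the per-block heritability
  around 0.03–0.13, the level at which a per-block bivariate REML at
  desk-scale sample sizes can still resolve the planted signal.
* `null` — 1 chromosome × 5 blocks × 40 SNPs at $n=200$ per population,
  $h^2=0.5$, all correlations zero, all genetic variance in the first
  block with every SNP of that block causal. Used for type-I-error
  calibration of the zero-covariance test on the variance-carrying block.
  The concentration and the all-causal architecture are deliberate: a
  calibration experiment must satisfy the assumptions of the test it
  calibrates. When instead many blocks share the variance, or causal
  variants are a sparse subset of the kernel's SNPs, the one-kernel block
  model is misspecified — polygenic background and architecture mismatch
  leak realized cross-population covariance into the tested parameter —
  and the likelihood-ratio test over-rejects even though the populations
  are truly independent (rates around 0.10–0.13 instead of 0.05 in our
  experiments). This is a property of single-kernel local tests, not of
  the optimizer, and is listed under limitations.

## Problem sizes used in the checks

The verification suite works at sizes a laptop handles in minutes:
parameter-recovery runs use 500 individuals per population and 2000 SNPs
(20 replicates); calibration uses 200 block-level tests at 300 per
population; the model-ranking experiment uses 20 replicates of the
heterogeneous preset with 3-fold cross-validation and classification
fixed per replicate. The acceptance script cross-validates all five
models on one heterogeneous dataset with 3 folds × 2 repeats and a
`topK` of 2 — one fifth of the blocks, the same fraction that the
top-20-of-several-hundred rule selects on dense real data.

## Known limitations

* Exactly two populations; residual covariance between them is fixed at
  zero (inestimable without doubly-measured individuals).
* The per-block REML estimator of local correlations is exact but has
  high variance when a block's heritability is small; with many blocks
  sharing a fixed total heritability, estimates saturate at $\pm 1$ and
  classification degrades toward noise. The significance-based scheme is
  more robust in that regime than the magnitude-based one.
* The per-block likelihood-ratio p-values inherit the one-kernel model's
  assumptions. Under strong polygenic background or sparse causal
  architectures the test is anti-conservative (see the `null` preset
  discussion above), so block p-values on real data are best read as a
  ranking device — exactly how the SIG/NON classification uses them —
  rather than as calibrated significance statements.
* The LD splitter scores genotype (unphased) correlation in a fixed SNP
  window; it is not a replica of any published block atlas, and block
  boundaries in weak-LD regions are arbitrary to within the window.
* GRMs are dense; memory is $O(n^2)$ and REML iterations $O(n^3)$.
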