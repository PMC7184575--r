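---
title: "Multi-kernel prediction of grain yield from genomic and physiological data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel prediction of grain yield from genomic and physiological data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grain yield in wheat is a complex trait with low heritability, strongly
shaped by genotype-by-environment interaction. Genomic selection predicts a
line's breeding value from genome-wide markers; phenomic prediction uses
inexpensive field physiology instead — chlorophyll content (SPAD), canopy
temperature (CT), membrane thermostability (MT), and the NDVI decay during
grain filling summarized as a senescence rate (RS) and a stay-green value
(SG). `mkblup` implements both sources of information, and their
environment interactions, as relationship kernels in one family of BLUP
models, so their predictive value can be compared and combined in
multi-environment trials of inbred panels.

## Models

All models act on least-squares means $y_{ij}$ of grain yield for genotype
$j$ in environment $i$, with the environment as a fixed effect. The six
forms combine up to two random effects:

$$y_{ij} = \mu + E_i + u_{1} + u_{2} + \varepsilon_{ij},$$

where each $u$ is one of

* a genomic main effect $G_j$ with $\mathbf{u}_G \sim N(0, \sigma^2_G
  \mathbf{G})$, $\mathbf{G} = \mathbf{X}\mathbf{X}'/n$ from the centered,
  standardized marker matrix $\mathbf{X}$ ($n$ markers);
* a physiological main effect $P_l$ with $\mathbf{u}_P \sim N(0, \sigma^2_P
  \mathbf{P})$, $\mathbf{P} = \mathbf{S}\mathbf{S}'/m$ from centered,
  standardized trait LSmeans $\mathbf{S}$ ($m$ traits);
* reaction-norm interactions $GE$ or $PE$ with covariance
  $(\mathbf{Z}_g \mathbf{K} \mathbf{Z}_g') \circ (\mathbf{Z}_E
  \mathbf{Z}_E')\,\sigma^2_{KE}$, the Hadamard product of the
  record-expanded line kernel and the same-environment indicator.

The six named forms are `G`, `G+GE`, `G+PE`, `P`, `P+PE`, `P+GE`
(`model_spec()`). Standardization uses the population (divide-by-N)
standard deviation so that the mean diagonal of each kernel is exactly 1;
this is a documented choice — with sample SDs every variance component is
simply rescaled by a constant close to 1.

## Fitting

`fit_mkblup()` runs a Gibbs sampler. Each kernel is eigendecomposed once
(eigenvalues below $10^{-8}$ of the maximum are dropped, giving
reduced-rank sampling in the kernel's column space) and its effects are
sampled in the eigenbasis, where the full conditional is diagonal. Variance
components have scaled-inverse-$\chi^2$ full conditionals with prior
degrees of freedom 5 and prior scale set so that, a priori, the phenotypic
variance splits equally across the components of the model — the standard
weakly-informative convention for this sampler family; both are
configurable (`chain_config()`). Records with missing response are handled
by data augmentation: they are excluded from the likelihood and refreshed
from the current model each sweep, which is exactly what lets whole lines
be masked across all environments during cross-validation while still being
predicted through the kernels.

Defaults are 12,000 iterations, 2,000 burn-in, thinning 5. For the
moderately sized problems in the examples and tests we use 3,000–8,000
iterations, which we found sufficient for the posterior means used here;
the effective-sample-size column of `varcomp` flags when a longer chain is
warranted. With variance components held fixed, the posterior mean of the
single-kernel model coincides with the closed-form mixed-model (BLUP)
solution — the package tests verify this to correlation above 0.999.

Residual variance is homogeneous across environments; environment-specific
residuals are a known limitation.

## Phenotype pipeline

`compute_lsmeans()` fits genotype as fixed and block (and environment, in
the joint model) as random via REML (`lme4`), optionally with days to
heading (DTH) as a fixed covariate to strip maturity confounding; LSmeans
are reported at the mean DTH. Per-environment fits are the default since
trait reporting in such trials is per environment; the joint model is
available. Broad-sense heritability uses the random-genotype, random-block
model per environment: $H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_e)$.
With un-replicated entries, the repeated checks of the augmented design
supply the error degrees of freedom.

Derived traits: $\mathrm{MT} = (1 - T_1/T_2)\times 100$ from conductivities
after heat treatment ($T_1$) and autoclaving ($T_2$); thermal time is the
cumulative clamped daily mean temperature above a base of 0 °C (a common
winter-wheat choice; the base is configurable); RS is the OLS slope of NDVI
against accumulated growing degree days; SG is the decay line evaluated at
the thermal time of physiological maturity. Out-of-range SG predictions are
returned with a warning rather than silently clipped.

Canopy temperature is a single value per plot; where a protocol records it
several times, the mean is the assumed aggregation. Trait-by-environment
gaps (a trait not scored in one environment) stay missing at this stage;
only inside `compute_physio_kernel()` are line-level gaps mean-imputed
(and logged), mirroring how such gaps must be bridged to form one P kernel
across environments. Which traits compose P is explicit in `traits=` —
the default takes every available physiological trait and excludes DTH.

## Cross-validation and selection response

`stratify_lines()` performs the clustering stage of a discriminant analysis
of principal components: PCA on standardized markers (components covering
80% of variance) followed by k-means into 10 groups. The discriminant step
is omitted because only the group memberships matter for fold construction.
`assign_folds()` assigns whole groups to 5 folds (largest group first into
the currently smallest fold, after a seeded shuffle), so related lines are
never split between training and validation. `cross_validate()` masks every
record of the validation lines, refits, and reports per environment the
mean predictive correlation $r_p$, the heritability-adjusted accuracy
$r_{GY} = r_p / \sqrt{H^2}$ and its standard error
$\sigma_{r_p}/\sqrt{f H^2}$. The heritability used for adjustment is that of
raw grain yield even when LSmeans are DTH-corrected (flagged in the
output). Response to selection follows the breeder's equation $R = H^2 S$
with $S$ the selection differential of the top 10% by GEBV
(size `ceiling(0.10 n)`, ties broken by line id); it is computed on each
fold's validation lines and aggregated with $\mathrm{SE} =
\sigma_{RTS}/\sqrt{f}$. Pooled out-of-fold GEBVs are also returned for
whole-panel selection.

## Trait importance

`tune_and_rank()` standardizes traits, centers yield (optionally after
regressing DTH out of it), and scans elastic-net penalties on a grid —
mixing values $\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$ and, per $\alpha$, 50
log-spaced $\lambda$ values spanning four decades below the smallest
all-zeroing penalty — by repeated 10-fold cross-validation with 20 repeats.
The pair with the smallest mean squared error wins (ties go to the stronger
penalty, then the sparser mixing value); importance is $100 |\beta_j| /
\max_k |\beta_k|$ from the full-data refit. The coordinate-descent solver
is implemented in the package with covariance updates and a $10^{-7}$
convergence threshold on the largest coefficient change; tests check it
against the ordinary-least-squares and soft-thresholding closed forms and
against an independent implementation.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe a soft-wheat diversity panel: 242 inbred
lines in 10 sub-populations (Balding–Nichols divergence, $F_{st} = 0.15$),
~19k GBS SNPs with 10% missing calls, four environments with an
un-replicated augmented design of 12 blocks and 3 repeated checks, and
variance components (60,000 / 30,000 / 120,000 (kg/ha)² for genetic, GE and
residual) giving a plot-level yield heritability near 0.33, inside the
0.20–0.41 range typical of such panels. QTL effects are drawn i.i.d. normal
and rescaled so the population variance of the true genetic values hits
$\sigma^2_G$ exactly, which makes parameter-recovery tests sharp. GE
deviations are i.i.d. per line-by-environment — exchangeable, with no
environmental covariates driving them. Physiological traits load linearly
on the true genetic-plus-GE value with noise levels chosen to reproduce
field-scale trait means, spreads and trait–yield correlations of roughly
0.2–0.4 in magnitude; NDVI follows a per-plot linear decay over six
thermal-time stamps between 400 and 1150 °C·day with maturity at
1300 °C·day. Block effects have SD 150 kg/ha; the generator leaves block
and check-adjustment magnitudes free because field reports rarely state
them.

What passing tests therefore show: the estimators recover the quantities
they claim under the stated model. What they cannot show: robustness to
spatial field trend, non-linear senescence, assay drift, or marker
ascertainment — none of which the generator simulates.

## Numerical choices and degenerate inputs

* Markers failing QC (> 80% missing or MAF < 0.05, boundaries retained)
  are removed before imputation; a zero-variance marker reaching
  `compute_grm()` is an error naming the marker.
* The allelic-independence filter (Fisher's exact test on
  presence/absence of the two alleles, retain at $P < 0.001$) is off by
  default because GBS pipelines apply it during SNP calling; the 2×2 table
  counts heterozygous, ref-only, alt-only and no-call lines — the
  presence/absence formulation is a documented choice. It runs before
  imputation, while heterozygote and missing-call information survives.
* Kernel PSD is enforced at $10^{-8}$ relative eigenvalue tolerance;
  interaction kernels are exactly zero across environments by
  construction.
* REML variance estimates from `lme4` are non-negative by construction;
  $H^2$ is therefore always in $[0, 1]$.
* Gibbs chains are reproducible from `chain_config(seed=)`; fold fits use
  `seed + fold`; pipeline stages use fixed offsets from the global seed.
* Selection-set ties at the GEBV cutoff are broken by line id, logged in
  the returned object's ordering.

## Problem sizes used in tests and examples

The shipped checks run on reduced panels chosen to exercise the full
pipeline at desk scale: 150 lines × 2,000 markers × 3 environments with
4,000-iteration chains for the cross-validation comparisons; 242 lines ×
3,000 markers × 4 environments with 3,000-iteration chains for
variance-component recovery; 40 lines for the closed-form BLUP
equivalence. These sizes are the package's own reference simulation; the
generator scales to the full ~19k-SNP panel unchanged.

## Known limitations

Homogeneous residual variance across environments; no factor-analytic GE
structure; no spatial adjustment of plots; the LD-aware imputation of a
production GBS pipeline is replaced by column-mean/major-allele imputation
behind the same interface, so any pre-imputed matrix can be supplied
instead.
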