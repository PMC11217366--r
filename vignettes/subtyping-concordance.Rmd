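---
title: "Comparing intrinsic breast-cancer subtyping methods: models, normalization and concordance"
author: "subtypeConcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing intrinsic breast-cancer subtyping methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypeConcord)
library(SummarizedExperiment)
```

## The models

Intrinsic subtyping treats a tumor's expression profile as a point in gene
space and asks which of five prototype profiles — LumA, LumB, HER2-E, BL,
NL — it most resembles. Two families of classifiers are implemented.

**Nearest-centroid.** Given a centered log-expression profile $x$ and
centroids $c_k$ over a shared gene set, the call is
$\arg\max_k \rho(x, c_k)$ with $\rho$ either Spearman rank correlation
(PAM50-style; ties receive average ranks) or Pearson correlation
(Prosigna-style, computed after housekeeping-gene normalization and
per-gene affine technical calibration — the role of Prosigna's "two sets of
scaling factors" in this package's decomposition). The full correlation
vector is retained, along with the top-two margin
$\delta = \rho_{(1)} - \rho_{(2)}$: a small $\delta$ marks a borderline
tumor whose subtype flips under small perturbations. Spearman calls are
invariant to any strictly increasing per-sample transformation; Pearson
calls to positive-slope affine maps. Both properties are enforced by
property-style tests.

**Binary-rule naive Bayes.** An AIMS-style classifier evaluates ordered
rules $b_r = [\mathrm{expr}(g^{low}_r) < \mathrm{expr}(g^{high}_r)]$ within
each sample and scores classes by
$\log \pi_k + \sum_r b_r \log p_{rk} + (1-b_r)\log(1-p_{rk})$, reporting
normalized posteriors. Because the rules only consult each sample's own
gene ordering, the call is "absolute": independent of cohort composition,
normalization, or any monotone distortion of the measurement scale. Rules
whose genes a targeted panel does not measure are dropped with
`subsetRules()` (the classifier then runs on the remaining rules), and
`trainRules()` fits a reference rule set on synthetic data; published rule
tables load through `readRuleSet()`.

## Normalization and centering

The pre-processing steps mirror what the platforms require:

* `log2CPM()` — probe/read counts to $\log_2(\mathrm{CPM}+1)$. The +1
  pseudocount keeps zero counts finite; the transform is otherwise the
  plain counts-per-million definition.
* `quantileNormalize()` — forces all samples onto the mean-of-order-
  statistics distribution (delegating to limma, ties averaged).
* `uqFPKM()` — upper-quartile FPKM: counts divided by gene length (kb) and
  the sample's 75th percentile of protein-coding counts, then
  $\log_2(\cdot+1)$. Zero-count protein-coding genes stay in the
  percentile computation; no exclusion rule is applied.
* `housekeepingNormalize()` — subtracts the per-sample mean of the
  housekeeping genes' log values, mathematically equivalent to dividing by
  their geometric mean on the linear scale. The log-scale form was chosen
  because every downstream step works on log expression.
* `applyCalibration()` / `fitCalibration()` — per-gene affine maps
  $y = a_g x + b_g$ on the log scale. Pretrained cross-platform factors
  are proprietary, so the factors are caller-supplied inputs; the fitting
  helper (per-gene ordinary least squares on paired samples) exists so the
  synthetic tests can close the loop.

**Composition-aware centering.** A centroid classifier expects data
centered the way its training cohort was — a mixed population. A trial
restricted to ER+/HER2− disease is mostly luminal, so naive per-gene
median centering subtracts something close to a luminal profile and
distorts every sample toward the boundary between luminal subtypes. Two
transfers of an external reference cohort's geometry fix this:

* sgPct (`buildSgPctReference()` + `sgPctCenter()`): for each gene, find
  the percentile $p_g$ of the reference *subgroup's* empirical
  distribution at which the *full* reference cohort's median sits; then
  center the trial cohort at its own empirical quantile at $p_g$. The
  reference records both medians and $p_g$, and verifies at construction
  that evaluating the subgroup quantile function at $p_g$ returns the
  global median (wherever $p_g$ is not clamped to 0 or 100).
* sgMd (`sgMdCenter()`): subtract the difference between the trial median
  and the reference subgroup median, i.e. move each gene's trial median
  onto the subgroup median.

Quantiles and their inverses use linear interpolation between closest
order statistics (R's type 7) on both sides of the sgPct transfer. No
particular convention is canonical here; what matters is that the forward
and inverse conventions match, which the self-consistency test (centering
the reference subgroup must subtract the reference global median, within
1e-9) pins down. Whether the percentile should be located in the
reference subgroup or in the test cohort is genuinely ambiguous in the
sgPct literature; this implementation locates it in the reference
subgroup and applies it to the test cohort, the reading that makes the
transfer independent of the test cohort's composition.

## Concordance statistics

`contingency()`, `overallAgreement()`, `cohensKappa()`,
`conditionalRates()`, `subtypeDistribution()` and `partitionDiscord()`
compare two call tables. Conventions, chosen to match how such results are
reported:

* Overall agreement is the diagonal over the labels the two methods share,
  computed on the *unmerged* table. Label merging (e.g. NL→LumA, when one
  method never emits NL) applies only to kappa, where a common label set
  is required; this is why an agreement of 119/222 can coexist with a
  kappa computed on a 4×4 merged table.
* Kappa is unweighted, $P_e$ from marginal products, with the large-sample
  standard error reported. The implementation is the direct formula and is
  cross-checked in the tests against an independent library
  implementation, plus a permutation calibration (mean kappa over 1000
  independent assignments with fixed marginals is 0 within Monte-Carlo
  error).
* Rounding follows reporting practice: agreement and conditional rates to
  integer percent, distributions to one decimal, kappa to two decimals —
  always half away from zero, with raw fractions retained alongside.
* Clear-defined samples are those with exactly matching calls (no
  merging); the rest are discord.

The borderline analysis (`topTwo()`, `switchToSecond()`,
`adjacencyAudit()`) re-assigns every sample with $\delta \le 0.1$ to its
second-closest centroid. The 0.1 threshold is interpreted on the
correlation scale as $\rho_{(1)} - \rho_{(2)} \le 0.1$, which is identical
to a 0.1 gap in correlation distances $1-\rho$. The audit labels each
switch adjacent or not under the biological ordering
LumA–LumB–HER2-E–BL; NL has no place in that ordering and triggers an
error rather than a silent guess.

## The synthetic generator

`simulationConfig()` fixes the study conditions; all generators are
deterministic functions of (config, seed).

* **Centroids** (`makeCentroids()`): unit-SD, mean-zero profiles whose
  empirical pairwise correlations *exactly* equal
  $0.6^{d}$, where $d$ is the distance along the line
  NL–LumA–LumB–HER2-E–BL (Gaussian draws are whitened and recolored by the
  Cholesky factor of the target matrix). Adjacent subtypes are thus more
  confusable than distant ones, reproducing the LumA–LumB and
  HER2-E–BL boundaries where real borderline calls concentrate.
* **Cohorts** (`simulateCohort()`): sample = centroid + i.i.d.
  $N(0, \sigma^2)$ per gene. Defaults: 50 genes (a classifier-panel-sized
  signature) and $\sigma = 1$, making per-gene noise comparable to the
  unit subtype signal — the regime where normalization choices visibly
  move calls; at $\sigma = 0$ recovery is exact by construction.
* **Compositions**: the reference cohort is mixed
  (LumA .30, LumB .20, HER2-E .12, BL .28, NL .10) with its ER+/HER2−-like
  subgroup defined as the LumA/LumB/NL samples — luminal-dominant by
  construction; the trial cohort is drawn from
  (LumA .55, LumB .35, HER2-E .08, BL .01, NL .01), the luminal dominance
  of an ER+/HER2− trial. Both cohorts share a per-gene baseline abundance
  $N(8, 1.5)$ so that centering is actually required.
* **Platform distortion** (`applyPlatformBias()`): per-gene affine
  distortion with scale $\sim$ lognormal(0, 0.15) — positive by
  construction — and shift $\sim N(0, 0.5)$; optionally a random
  increasing piecewise-linear map per sample (5 lognormal-slope segments)
  to exercise rank-invariance claims without inventing platform physics.
  The drawn parameters are returned so tests can invert them.

`makeTrialScenario()` bundles all of this; in that scenario sgPct/sgMd
centering against the reference beats naive within-trial median centering
by a wide margin (the acceptance suite averages 10 seeds), and
cross-scheme discordance measured by kappa grows as the platform-bias
magnitude grows.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: gene–gene correlation within a subtype (noise is
i.i.d. across genes), count-level sampling noise and library-size
variation, intra-tumor heterogeneity and normal-cell contamination,
missing values, and real centroid geometry (the published centroid values
are loadable as inputs but are not bundled). Results on synthetic cohorts
demonstrate internal consistency of the pipeline, not clinical
performance.

## Numerical choices and degenerate inputs

* Rule evaluation uses strict inequality; equal values make the rule
  false. Deterministic, and consistent with "less than" semantics.
* Correlation ties within 1e-12 of the maximum are broken by a
  configurable preference order (default LumA, LumB, HER2-E, BL, NL) and
  always flagged, never silent.
* Rule-classifier priors default to uniform: a single-sample "absolute"
  assignment should not encode the training cohort's composition.
  Conditional probabilities are smoothed (additive, one pseudo-count) so
  no log-probability is infinite; unsmoothed tables are rejected at load.
* Classifier genes missing from the data are dropped pairwise — the
  correlation is computed over the gene intersection (a 49-of-50 overlap
  is routine on targeted panels); imputation would invent data. A minimum
  overlap (`minGenes`, default 10) guards against degenerate calls.
* Zero-variance sample profiles, zero library sizes, zero upper-quartile
  counts, empty gene intersections and degenerate marginals (expected
  agreement 1) raise errors naming the offending sample/gene rather than
  propagating NaN.
* `trainRules()` selects rules round-robin across classes by one-vs-rest
  information gain: a globally top-scoring list can consist entirely of
  rules separating the same easy class, leaving two similar classes
  unseparated.

## Problem sizes

The test and acceptance runs use cohorts of 40–300 samples over 50-gene
signatures, 10-seed averages for the centering comparison, 1000
permutations for the kappa null, and 1000 random monotone maps for the
invariance checks — sizes at which the Monte-Carlo error of every assertion
is far smaller than the effect it checks, while the full suite runs in
well under a minute.

## Limitations

The published PAM50/Prosigna centroid values, the AIMS 100-rule parameters
and the trials' expression data are not redistributable and are therefore
inputs, not fixtures: the packaged tables are limited to the published
cross-classification counts. Conclusions about real cohorts require
loading those assets through the documented formats. Kappa's large-sample
standard error is reported but no significance machinery beyond it is
provided, and survival endpoints are out of scope.
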