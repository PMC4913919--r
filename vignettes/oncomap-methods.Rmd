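---
title: "oncomap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oncomap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomap)
```

## The problem

Large public compendia of expression arrays pool samples from hundreds of
experiments, tissue types and disease states. Pooling buys power to detect
small but systematic expression changes between cancer and normal tissue —
changes too subtle to reach significance in any single study — but only if
the analysis absorbs the two dominant nuisance axes of such data: the
tissue of origin and the experiment (laboratory, batch) each array came
from. `oncomap` implements the full chain from annotated expression matrix
to a validated list of disease-associated probesets, with a synthetic-data
generator matched to the model so every stage can be verified against
known truth.

## The data container

An `AnnotatedExpressionSet` extends `SummarizedExperiment`: a probesets ×
samples matrix of log2 intensities (assay `"exprs"`) plus per-sample
`biological_group`, `tissue`, `experiment` and `disease_status` columns.
Disease status is a closed vocabulary (`normal`, `cancer`, `other`);
validity checks reject missing values, duplicated identifiers and unknown
labels at construction, so modelling code never has to re-validate.

Subset construction mirrors common compendium practice:
`filterMinGroupSize()` keeps biological groups with at least `min_n`
members (default 20) for the map stage; `selectPairedTissues()` keeps
tissues with at least `min_n` samples in *both* disease classes, dropping
`other`, for the modelling stage; `selectMostVariable()` reduces to the
`n` probesets with the largest sample variance (unbiased, across all
retained samples; ties broken by input order so the reduction is
reproducible).

## The group-level map

Two complementary reductions describe compendium structure at the level of
biological groups:

* **Similarity**: for groups $G_m, G_n$, the mean Pearson correlation over
  all sample pairs,
  $\mathrm{sim}(G_m,G_n) = \sum_{s\in G_m}\sum_{s'\in G_n}
  \mathrm{cor}(s,s') / (|G_m||G_n|)$. The diagonal uses the same formula
  (self-pairs included), so it is below 1 for heterogeneous groups; it is
  reported but ignored by clustering. `clusterGroups()` runs agglomerative
  clustering on $d = 1 - \mathrm{sim}$ (average linkage by default;
  complete and single are selectable — the choice is exposed because no
  single linkage is canonical for correlation maps).
* **Group means**: $Y_{mn}$, the mean expression of probeset $m$ in group
  $n$, for biclustering probesets against groups.

`pcaMap()` treats samples as statistical units and probesets as variables,
centred but not scaled (log2 expression is already on one scale; scaling
would up-weight flat probesets). Each axis is oriented so its
largest-magnitude loading is positive — principal axes are sign-ambiguous
and a fixed convention keeps runs comparable. Components past the matrix
rank are zero-padded and flagged rather than fabricated.

## Variability screening

For a grouping of the paired subset into $G$ conditions (by default the
tissue × disease-status cells) with sizes $N_n$, per-probeset:

$$BGV(p) = \frac{\sum_{n=1}^G N_n\,(\bar y_n(p) - \bar y(p))^2}{G - 1},$$

with $\bar y(p)$ the grand mean over all samples (equivalently the
size-weighted mean of group means). Probesets above the Tukey upper
whisker $Q_3 + 1.5\,IQR$ of the BGV distribution (linear-interpolation
quantiles) are flagged as drastically variable. The deviation count — the
number of groups with $\bar y_n \pm \sigma_n$ strictly on one side of
$\bar y$ — quantifies how many conditions shift a probeset at all. Group
standard deviations use the population convention (divide by $N_n$) so
singleton groups contribute 0 rather than an undefined value; the sample
convention is available as an option.

## The crossed mixed-effects model

Per probeset, expression in sample $(i,j,k)$ (disease status $i$, tissue
$j$, experiment $k$) is modelled as

$$y_{ijk} = \mu + \beta\,\mathbb{1}[i=\text{cancer}] + t_j + t_{ij} + e_k
+ e_{ik} + \epsilon_{ijk},$$

with independent normal random intercepts for tissue, tissue × disease,
experiment and experiment × disease (variances $\sigma_t^2,
\sigma_{t\delta}^2, \sigma_e^2, \sigma_{e\delta}^2$) and residual variance
$\sigma^2$. Tissue and experiment are treated as crossed factors; $\beta$
(log2 units, coded 0 = normal, 1 = cancer, so $\beta > 0$ means higher in
cancer) is the tissue-independent disease effect of interest. Because
tissue is random, inference about $\beta$ generalizes beyond the tissues
present in the data.

**Estimation.** Profiled REML: the four variance *ratios*
$\gamma_r = \sigma_r^2/\sigma^2$ are optimized on the log scale (bounds
$[10^{-10}, 10^6]$) by the PORT quasi-Newton routine (`nlminb`) from the
fixed start $\gamma = 1$ (every component at the method-of-moments
residual scale), making fits deterministic. The criterion is evaluated in
compiled code: with $V_0 = I + Z\Gamma Z'$, the Woodbury identity reduces
each evaluation to the $q\times q$ system $M = I + \Gamma^{1/2}Z'Z
\Gamma^{1/2}$, independent of sample count; because experiments nest in
tissues in practice, the random-effect columns split into connected
components (one small block per tissue) and $M$ factorizes blockwise. A
genuinely crossed design degrades gracefully to one dense block. Residual
sums of squares are floored at $10^{-12}$ so exactly interpolable
(noise-free) data remain well-defined; estimated ratios at the lower
bound are reported as exact zeros. $\hat\beta$ and its standard error
come from generalized least squares at the estimated components;
`fitProbeset(..., varcomps = )` bypasses REML and fits at user-fixed
components, which is also the hook the test suite uses to compare against
a dense GLS oracle ($10^{-6}$ relative agreement; `lme4` agrees to about
six significant digits on the same fixtures).

**Testing.** $t = \hat\beta / se(\hat\beta)$ is referred to a
$t$-distribution with $N - 2$ degrees of freedom (observations minus
fixed-effect parameters). This df is an upper bound and anti-conservative
when random-effect levels are few or classes small; the pipeline therefore
only models designs with at least 20 replicates per tissue × status class,
which is also the regime in which the test suite asserts null
calibration. Benjamini–Hochberg adjustment (step-up, via `p.adjust`) runs
across all converged probesets at the restrictive level $\alpha = 0.01$;
non-converged probesets are excluded from adjustment and counted, never
silently assigned $p = 1$.

## Permutation inference and plug-in FDR

`runPermutationTest()` permutes disease labels uniformly **within each
tissue** (preserving the label multiset per tissue; a stricter
within-experiment scope is available), refits every probeset on each of
$B$ permutations, and computes:

* empirical p-values: the plain fraction of permuted $|t|$ at least as
  extreme as the observed one (ties count; two-sided via $|t|$, so any
  monotone transform of the statistic gives identical p-values). The
  fraction is $\#/B$, so 0 is attainable; a $(\#+1)/(B+1)$ correction is
  available but off by default. Non-converged permutation fits are
  skipped for that probeset with the denominator reduced and the skip
  counted;
* $F$: the mean number of BH-significant probesets per permutation — the
  expected false-positive count of the whole fit–test–adjust pipeline;
* $\hat\pi_0 = \#\{p_i > \lambda\}/((1-\lambda)m)$ with $\lambda = 0.5$
  from the observed model p-values, clipped to $(0,1]$ and floored at
  $(1/m)/(1-\lambda)$ (flagged) when no p-value exceeds $\lambda$;
* the plug-in estimate $\widehat{FDR} = \hat\pi_0 F / S$, with $S$ the
  observed significant count. At $S = 0$ the estimator is undefined and
  reported as `NA` rather than a fabricated zero.

`qqExport()` pairs sorted $-\log_{10}$ adjusted p-values of the observed
fit with those of a shuffled-label fit at matching quantiles;
`volcanoExport()` writes $(\hat\beta, -\log_{10}p)$.

## Gene-list validation

`collapseToGenes()` splits significant probesets into unique genes,
composite multi-matchings (joined with `" /// "`, the platform
convention, and excluded from unique-gene overlap counts) and unmapped
probesets. `hypergeometricOverlap()` computes $P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$ via `phyper(log.p = TRUE)`, keeping
precision at extreme tails (validated against direct summation to six
significant digits). The universe is always supplied explicitly — it is a
property of the platform, not of the gene sets — and
`overrepresentation()` tests each set in both directions with BH
adjustment across all set × direction tests at 0.05.

## The synthetic-data generator

`simulateDataset()` draws data *exactly* from the model above: per
probeset, fresh independent normal draws for every random term; $\mu_p$
uniform on a configurable log2 range (default 4–12, the bulk of observed
probeset means on this platform); a sparse fraction of probesets carry a
nonzero $\beta$ drawn as a ±|effect| mixture (magnitude normal around
`beta_location`), so volcano symmetry is checkable. Samples are assigned
to experiments round-robin within tissue, so every experiment contains
both disease classes and each experiment belongs to one tissue — the
nesting real compendia exhibit, while the fitter still treats experiment
as crossed. `defaultTissueSizes()` reproduces the 15 paired-tissue group
sizes of the real compendium design (5,938 samples), with a scale factor
for desk-scale runs. `simulateNull()` forces every $\beta$ to zero.

Default variance components ($\sigma_t^2 = 1$,
$\sigma_{t\delta}^2 = 0.25$, $\sigma_e^2 = 0.5$,
$\sigma_{e\delta}^2 = 0.1$, $\sigma^2 = 0.5$) put tissue identity first,
laboratory effects second and measurement noise at the scale of
within-group log2 spread seen in practice. `var_residual = 0` is accepted
so exact, noise-free fixtures can be constructed (the fitter's own
residual estimate remains strictly positive via the RSS floor).

What the generator does **not** emulate: probe-level intensities,
normalisation artefacts, batch effects beyond the experiment intercepts,
heavy-tailed or heteroscedastic noise, and cross-probeset correlation
(the model is fitted per probeset, so none is needed for calibration
checks). Passing tests on synthetic data therefore certify the
*machinery* — estimation, testing, permutation accounting — not the
distributional adequacy of the model for any particular real compendium.

## Problem sizes and numerical choices

The test suite exercises the pipeline at desk scale, chosen to keep full
runs in minutes while preserving the conditions the approximations need:

* *Null calibration*: 15 tissues (the compendium's panel width) at the
  minimum admissible class size (20 cancer + 20 normal), two experiments
  per tissue, 200 probesets; 20 seeded repetitions for type-I counts and
  one $B = 200$ permutation run for the observed-vs-permuted comparison.
  The panel width matters: with only 4–8 tissues the $N-2$ df rule is
  visibly anti-conservative — which is a property of the approximation,
  not the fitter, and the reason the method restricts itself to designs
  with many classes of at least 20 replicates. The permutation comparison
  additionally requires a *fully* null generator — $\beta = 0$ **and**
  $\sigma_{t\delta}^2 = \sigma_{e\delta}^2 = 0$ — because nonzero
  disease-interaction variances mean the labels still index real
  (mean-zero) random effects: they are then not exchangeable within
  tissue, and the permutation null genuinely differs from the observed
  distribution. This is worth remembering when interpreting
  permutation-based FDR estimates on real compendia, where such
  interactions surely exist. A related artifact: comparing BH-*adjusted*
  null p-values between two runs with a KS test always rejects, because
  the step-up adjustment piles most of each realization onto a tie
  plateau at a realization-specific value; distributional agreement is
  therefore asserted on the raw p-values, with robust summaries (median,
  tail mass) on the adjusted scale.
* *Parameter recovery*: the 15-tissue design scaled to ~600 samples
  (scale 0.1, three experiments per tissue), 100 probesets with effect
  magnitude 1; recovery is judged on the sign-corrected mean
  $\hat\beta \cdot \mathrm{sign}(\beta)$ because the generator draws
  two-sided effects.
* *Spiked signal*: 8 tissues × 40 samples, 10% nonnull at $|\beta| =
  3\sigma$, $B = 100$, for permutation/model agreement and export
  structure.

Numerical conventions collected in one place: REML convergence tolerance
$10^{-9}$ (relative; $10^{-8}$ inside permutation loops), RSS floor
$10^{-12}$, variance-ratio bounds $[10^{-10}, 10^6]$ on the log scale,
quantile type 7 (linear interpolation) for whiskers and QQ pairing,
stable tie-breaking by input order wherever an order matters, and a
single master seed fanned out deterministically to per-stage child seeds
in `runFullPipeline()` so stages can be rerun in isolation.

## Known limitations

* The $N - 2$ df rule is deliberately the only option (kept for parity
  with the method as published); Satterthwaite or Kenward–Roger df would
  be better calibrated for small panels but answer a different question.
* Empirical p-values at resolution $1/B$ make very small $B$ unusable for
  tail inference; the default desk-scale $B = 200$ is for calibration
  checks, and compendium-scale runs should use $B$ in the thousands.
* The permutation engine refits the full model per draw; runtime scales
  linearly in $B \times$ probesets (seconds per thousand fits at desk
  scale thanks to the blockwise factorization).
* `other` disease states are never modelled, only carried in the
  container; treatment-status curation is assumed done upstream in the
  annotation file.
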