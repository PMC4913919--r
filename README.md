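# oncomap

Meta-analysis machinery for finding **tissue-independent cancer expression
changes** in large annotated microarray compendia.

Public repositories hold tens of thousands of Affymetrix HG-U133Plus2
arrays spanning hundreds of laboratories, tissue types and disease states.
Pooling them buys enormous statistical power, but any honest analysis must
absorb the nuisance structure that comes with pooling: tissue of origin and
the experiment (laboratory) a sample came from both move expression far
more than disease status does. `oncomap` implements, end to end, a pipeline
for this setting:

* an annotated expression container (`AnnotatedExpressionSet`, built on
  `SummarizedExperiment`) carrying per-sample biological group, tissue,
  experiment and disease-status labels, with strict validity checks;
* group-level map tools: the average-correlation similarity between
  biological groups, the group-mean ("dimension-reduced") matrix,
  hierarchical clustering and a centred PCA of samples;
* between-group variance (BGV) screening and a deviation-count statistic
  that quantify how sharply each probeset moves across conditions;
* the core model: a per-probeset **crossed mixed-effects linear model**

      y_ijk = mu + beta * 1[i = cancer] + t_j + t_ij + e_k + e_ik + eps_ijk

  with random intercepts for tissue (`t_j`), tissue x disease (`t_ij`),
  experiment (`e_k`) and experiment x disease (`e_ik`), fitted per probeset
  by profiled REML (compiled hot path; equivalent results to `lme4` to ~6
  significant digits). The disease effect is tested with the approximate
  Wald ratio `t = beta_hat / se(beta_hat)` on `N - 2` degrees of freedom,
  with Benjamini-Hochberg adjustment at a restrictive level (0.01);
* within-tissue label-permutation inference: empirical p-values, the
  permutation-expected false-positive count `F`, the null-proportion
  estimate `pi0 = #{p > lambda} / ((1 - lambda) m)` and the plug-in
  estimator `FDR = pi0 * F / S`;
* hypergeometric validation of the resulting gene list against external
  gene sets (GMT), with probeset-to-gene collapsing that separates unique
  genes from multiple matchings;
* a synthetic-data generator with exactly the model's variance-component
  structure and known ground truth, so every stage is testable without any
  download.

## Worked example

Simulate a desk-scale compendium (15 paired tissues, 20 cancer + 20 normal
each, two experiments per tissue) with 10% of probesets carrying a true
disease effect, then run the model and permutation stages:

```r
library(oncomap)

ts  <- data.frame(tissue = sprintf("t%02d", 1:15),
                  n_cancer = 20L, n_normal = 20L)
cfg <- simulationConfig(n_probesets = 100, tissue_sizes = ts,
                        experiments_per_tissue = 2L,
                        beta_nonnull_fraction = 0.1,
                        beta_location = 2, beta_scale = 0.1, seed = 7)
sim    <- simulateDataset(cfg)
paired <- selectPairedTissues(sim$es, min_n = 20)

res <- fitAll(paired, alpha = 0.01)
res
#> SignificanceTable: 100 probesets, alpha = 0.01
#>   significant: 10  non-converged: 0

perm <- runPermutationTest(paired, B = 50, alpha = 0.01, seed = 8,
                           observed = res)
perm
#> PermutationResult: B = 50
#>   S = 10, F_hat = 0, pi0 = 0.8, FDR estimate = 0
```

All ten spiked probesets are recovered (`significant: 10`), no null
probeset is called, none of the 50 label permutations produces a single
significant probeset (`F_hat = 0`), and the plug-in estimate
`pi0 * F / S` is therefore 0 — the permutation scheme finds nothing to
doubt in the ten calls. `volcanoExport(res)` and
`qqExport()` produce the effect-size/evidence and observed-vs-permuted
quantile tables; `runFullPipeline(pipelineConfig(...))` chains every stage
(subset, map, BGV, model, permutation, validation) into a reproducible
artifact directory with a JSON run summary.

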