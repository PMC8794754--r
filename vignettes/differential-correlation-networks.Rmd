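---
title: "Differential correlation networks: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation networks: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The problem

Classical differential-expression analysis asks which genes change their
*mean* between tumor and normal tissue. dcnet targets a complementary
signal: gene pairs that change their *correlation* between the two
conditions. The extreme case is the "switching mechanism" — a pair that is
strongly positively correlated in one condition and strongly negatively
correlated in the other. Such pairs are invisible to mean-based tests but
point at rewired regulation.

The pipeline follows the two-stage design common in this literature:

1. **Filter by co-expression module.** A weighted gene co-expression
   network (WGCNA-style) partitions the transcriptome into modules;
   only modules tied to the phenotype are carried forward. This reduces
   the pair space from all \(\binom{p}{2}\) pairs to within-module pairs.
2. **Test pairs within selected modules.** Every within-module pair is
   tested for a correlation difference between conditions with the Fisher
   z statistic; the local false discovery rate (lfdr) controls multiplicity;
   surviving sign-flipped pairs with \(|r| > 0.5\) in both conditions form
   the switch network.

Clinical validation statistics (Kaplan–Meier, log-rank, a minimum-p
expression-cutoff scan, and 2×2 chi-square association tables) close the
loop from network hubs to outcomes.

## Models and statistics

### Co-expression network

Pairwise similarity is Pearson correlation by default (biweight
midcorrelation available via `method = "bicor"`; one method is used
consistently per run). The unsigned adjacency is
\(a_{ij} = |r_{ij}|^{\beta}\) (signed variant
\(((1+r)/2)^{\beta}\) available). The power \(\beta\) is chosen as the
smallest candidate whose **scale-free topology fit** reaches \(R^2 \ge 0.9\):
connectivities \(k_i = \sum_j a_{ij}\) are binned into 10 equal-width bins
and \(\log_{10}\) frequency is regressed on \(\log_{10}\) mean connectivity;
the index is \(R^2 \times (-\operatorname{sign}(\text{slope}))\) so it is
positive only when frequency decays with connectivity. When no candidate
reaches the target, the argmax is used and flagged — on small simulated
datasets with two planted modules the connectivity distribution is bimodal
rather than scale-free, so this fallback is the *expected* path there (see
"What a green test establishes" below).

One deliberate deviation: the binning is **equal-width**, not equal-count.
Equal-count bins force every bin's frequency to be (nearly) identical,
which makes the frequency-on-connectivity regression degenerate by
construction; equal-width binning is also what the established WGCNA
implementation uses.

The topological overlap
\[
\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
                       {\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_u a_{iu} a_{uj},
\]
measures shared neighborhood; genes are clustered by average linkage on
\(1 - \mathrm{TOM}\). Modules come from a **tree-variant static cut**: the
dendrogram is cut at a fraction of its maximum merge height
(0.95/0.97/0.99/0.995 for `deepSplit` 0–3) and branches with at least
`minModuleSize` (default 30) leaves become modules; everything else is
grey. The full hybrid dynamic tree cut with its PAM stage is deliberately
not reimplemented — its published description leaves the PAM stage
under-determined — and the simplification is validated by planted-module
recovery (adjusted Rand index ≥ 0.9 on the generator defaults, tested).

Module eigengenes are first principal components of the z-scored module
submatrix, unit-variance scaled and sign-aligned with mean module
expression. Modules whose eigengenes correlate above \(1 - \)
`mergeCutHeight` \(= 0.75\) are merged iteratively. Module relevance uses
two strict thresholds: |eigengene–trait correlation| > 0.5 and
within-module cor(MM, |GS|) > 0.5, where MM is a gene's correlation with
its own eigengene and GS its correlation with the trait. The
"|ME| > 0.5" selection rule is read as a threshold on the
eigengene–trait *correlation*; a literal threshold on eigengene magnitude
would be dimensionless and unusable. GS enters the MM–GS summary in
absolute value so that modules anti-correlated with the trait are scored
symmetrically.

### Differential correlation

For a pair with per-condition correlations \(r_A\) (normal, \(n_A\)
samples) and \(r_B\) (tumor, \(n_B\)):
\[
z_\bullet = \tfrac12 \log\frac{1+r_\bullet}{1-r_\bullet}, \qquad
Z = \frac{z_A - z_B}{\sqrt{\frac{1}{n_A-3} + \frac{1}{n_B-3}}},
\]
with a two-sided normal p-value. Correlations at exactly ±1 are clamped to
±(1 − 1e−12) with a warning rather than erroring, so noiseless fixtures
run. The test needs \(n > 3\) per condition — hence the generator's
minimum of 4 samples per arm.

**Local fdr.** The lfdr estimator is Efron-style empirical-null: the
marginal density \(f(z)\) of the pair statistics is fit by Poisson
regression of histogram counts (120 bins) on a natural-spline basis
(df 7); the null component is recovered by *central matching* — a
quadratic fit to \(\log f\) on the interquartile z-range yields the null
mean, sd and proportion \(\pi_0\) — and
\(\mathrm{lfdr}(z) = \pi_0\,\hat\varphi_0(z)/\hat f(z)\), clipped to
\([0,1]\). With fewer than 100 records the density fit is unreliable, so
the estimator falls back to Benjamini–Hochberg adjusted p-values, stored
in the same column and flagged in the `lfdr_method` attribute. If the
central quadratic is degenerate (non-concave), the theoretical N(0,1)
null is assumed. No floor is imposed on lfdr values; ties in published
tables of this kind may reflect estimator floors but that is not forced
here.

Ranking of "top pairs" filters lfdr < 0.05 and sorts by lfdr, then |Z|
descending, then gene ids — the tie-break is our choice, since ties at
identical lfdr are common and no ordering rule is published.

**Switch filter.** A pair switches when \(r_1 r_2 < 0\) *and*
\(\min(|r_1|, |r_2|) > 0.5\), both strict. The strict two-sided reading is
supported by published survivor lists in which pairs with one |r| just
below 0.5 are dropped. The displayed edge sign is the tumor-condition
correlation sign (the condition a single-sign network display most
plausibly reflects; recorded as an interpretation).

Node direction comes from a Welch two-sample t-test with BH adjustment —
an explicit, documented replacement for limma's moderated t: direction
only colors nodes, it selects nothing, so empirical-Bayes moderation
buys little here.

Optional per-condition pre-scaling (auto, Pareto, range, …) is *not*
applied by default: Pearson correlation is invariant to per-gene affine
scaling, so these transforms only matter for the PCA summaries.

### Clinical statistics

Kaplan–Meier estimation and the two-group log-rank test are implemented
from the product-limit and O/E/V definitions (and cross-checked against
the survival package in the test-suite). The **cutoff scan** dichotomizes
expression at every integer percentile 5–95 — exactly 91 candidate
cutoffs — using linear-interpolation quantiles with the low group defined
by expression ≤ cutoff; cutoffs leaving a group empty or event-free are
skipped but recorded. The best cutoff minimizes the log-rank p with ties
broken toward the 50th percentile (stability). The scan's minimum-p is
**selection-biased** (under the null its median sits near 0.05 at
n = 300, not 0.5 — the test-suite measures this); the result carries an
explicit `selection_bias_uncorrected` flag and no correction, mirroring
standard practice in the application literature.

The 2×2 chi-square uses the closed form
\(N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))\) **without** continuity
correction: this convention reproduces all six published
clinicopathological p-values (0.031, 0.027, 0.009, 0.047, 0.002, 0.034)
to printed precision, whereas Yates' correction does not. Verified in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the statistical
structure the analysis assumes, with ground truth attached.

* **Modules.** Each module has a latent factor
  \(f_m = \sqrt{1-\rho^2}\, g + \rho\, t\) (standardized condition
  indicator \(t\), shared Gaussian \(g\)), so \(\mathrm{cor}(f_m, t)
  \approx \rho =\) `module_trait_cor`. Genes load on the factor with
  loadings Uniform(0.8, 1.2) plus N(0, `noise_sd`²) noise. Defaults: two
  modules of 50 genes, \(\rho = (0.7, -0.7)\) (one module up, one down in
  tumor — the pattern real module–trait heatmaps show), noise_sd 0.3.
* **Switched pairs.** Pairs are organized into hubs of `switch_hub_size`
  (default 5) partners. The hub gene carries a private unit-variance
  factor \(u\); each partner loads \(-u\) in condition A and \(+u\) in
  condition B, with independent noise of variance \(1/s - 1\) so each
  (hub, partner) pair's population correlation is exactly \(\mp s\)
  (`switch_strength`, default 0.7). Defaults give 10 pairs in 2 hubs —
  the hub-and-spokes shape that dominant genes display in real
  differential-correlation networks and what makes degree-based hub
  recovery testable.
* **Background.** Remaining genes are i.i.d. N(0, 1). All genes then
  receive a per-gene baseline ~ N(6, 2), the log2-intensity offsets that
  make *inter-sample* correlations realistically high (~0.9) without
  affecting any gene–gene correlation; sample-outlier detection is only
  meaningful against this backdrop.
* **Sample sizes.** Defaults 100 normal + 300 tumor, the two-condition
  imbalance typical of tumor/normal cohorts of this kind.
* **Survival.** `simulate_survival()` draws exponential event times with
  rate \(\lambda_0 e^{\beta z}\) (z-scored expression, proportional
  hazards by construction), exponential censoring (default rates 0.1 and
  0.05, i.e. roughly two-thirds observed events), so a positive \(\beta\)
  makes high expression prognostically bad.
* **Reproducibility.** All randomness flows from one seed through named
  substreams (one per module, hub, background block, …), so enlarging one
  component never perturbs another, and generation is a pure function of
  the config. `.Random.seed` of the caller is restored.

### What the generator does *not* emulate

Probe-level microarray artifacts, batch effects, normalization residue,
heavy-tailed noise, overlapping module membership, and correlated
background genes. Consequently a green planted-recovery test establishes
that the implementation recovers the structure it targets under the
factor-model assumptions — it does not certify performance on real GEO
or TCGA cohorts, and the published real-data counts (module totals,
per-module switched-pair counts, specific module–trait correlations) are
deliberately not acceptance claims at this scale.

One structural consequence worth knowing: planted switched-pair genes are
*module-free* by construction (the size invariant keeps module genes and
switch genes disjoint), while the end-to-end pipeline — faithful to the
published flow — tests pairs only *within selected modules*. A default
end-to-end run on generator output therefore reports an empty switch
network; switched-pair recovery is exercised by running
`pairwise_differential_correlations()` over the full gene set, which is
exactly what the acceptance suite does.

## Numerical choices and degenerate inputs

* Correlation p-values use the exact t-transform
  \(t = r\sqrt{(n-2)/(1-r^2)}\), not the Fisher approximation — fixtures
  are as small as n = 6.
* TOM guards its denominator at 1e−12; for adjacency entries in [0, 1)
  the denominator cannot otherwise vanish.
* Bicor uses tuning constant 9 on MAD-standardized deviations; a gene
  with MAD = 0 falls back to its Pearson row/column with a warning.
* Missing values: pairwise-complete observations throughout (documented
  choice; the QC stage caps per-gene/per-sample missingness at 50%
  first).
* Outlier flagging standardizes connectivity *within* condition groups by
  default: the tumor/normal separation itself depresses the minority
  group's inter-sample correlations, and a pooled z-score would flag
  dozens of perfectly normal samples (we measured this on the generator).
  Even within-group, connectivity is left-skewed, so on homogeneous data
  a z < −2.5 rule flags on the order of 2–3% of samples; flagging and
  exclusion are therefore separate calls, and the pipeline logs what it
  drops.
* Eigengene sign: aligned to positive correlation with the module's mean
  expression profile; the two-gene module \(\{v, -v\}\) resolves through
  the same rule.
* Module labels are assigned by decreasing size ("M1" largest); tied
  merge heights in average linkage resolve by stats::hclust's
  deterministic ordering.

## Known limitations

* The static tree cut can split one planted module into two branches on
  unlucky seeds more readily than the hybrid dynamic cut would; the
  merge stage usually heals this, and recovery is tested over 10 seeds.
* The empirical-null lfdr needs a few hundred statistics to be stable;
  below 100 it falls back to BH (flagged), and with very high signal
  fractions central matching can misestimate \(\pi_0\).
* The scale-free target R² ≥ 0.9 is routinely unreachable on small
  planted-module toys (bimodal connectivity); the argmax fallback with a
  warning is the designed behavior, not an error.
* The minimum-p cutoff scan is reported uncorrected (with a caveat flag);
  treat its p-values as exploratory, exactly as its users in the
  application literature should.
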