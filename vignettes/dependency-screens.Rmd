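---
title: "Classifying and comparing gene dependencies across perturbation modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and comparing gene dependencies across perturbation modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcompare)
```

## The problem

Genome-scale loss-of-function screens measure, for each gene in each cancer
cell line, how much cell viability drops when the gene is perturbed. Two
perturbation modalities dominate: complete knockout (CRISPR-like, strong
efficacy) and partial knockdown (RNAi-like, weaker but graded). Processed
screens are summarized as a *gene effect*: a continuous score per
(cell line, gene), scaled so the median of nonessential control genes is 0
and the median of core-essential controls is -1; more negative means
stronger dependency.

`depcompare` implements the analysis layer that sits on top of such
matrices: screen quality control, per-gene dependency classification,
cross-dataset agreement, biomarker modeling, drug--dependency association,
and co-dependency network fusion — together with a synthetic-screen
generator whose planted ground truth lets every step be validated
end-to-end.

## The synthetic screen generator

`synth_config()` / `synth_bundle()` emulate a matched two-modality screen
collection. Defaults describe a realistic matched panel: 400 cell lines,
1000 genes, per-entry noise SD 0.15 in scaled gene-effect units.
Five dependency archetypes are planted (fractions 10/10/10/10/60%):

* **pan-dependent** — Normal(-1, 0.15) in every line;
* **strongly selective** — null in most lines, Normal(-1.5, 0.15) in a
  5% minority, giving the negatively skewed mixture the selectivity test
  targets. The skew is produced by a two-component mixture rather than by
  sampling a literal skew-t: it is simpler, and detecting it is a strictly
  harder task for a skew-t likelihood-ratio test;
* **high-variance** — a continuous gradient `effect = -u`, with
  `u ~ Beta(2, 5)` per line: most lines weakly dependent, a minority
  strongly, which also yields the negative sample skewness typical of this
  class;
* **weakly selective** — the marginal distribution of this class is not
  pinned down by published analyses; we treat these genes as selective
  dependencies with sub-threshold depth (default 0.45 of the pan depth in
  10% of lines);
* **non-dependent** — pure noise around 0.

Modality B ("knockdown-like") attenuates every planted depth by a
multiplicative factor (default 0.6) and additionally inflates the variance
of pan-dependent genes (additive SD 0.2). This reproduces the qualitative
cross-modality pattern — knockout pan-dependencies become graded,
higher-variance profiles under knockdown — without claiming a mechanistic
model of either perturbation.

Around the effect matrices the bundle plants: reagent-level matrices (per
reagent bias, noise, and a configurable off-target fraction whose reagents
report an unrelated gene); omics features coupled to dependency through
four biomarker mechanisms (mutation driver, expression addiction, paralog
loss, CYCLOPS copy-number sensitivity); a dose-level drug tensor in which
mid-range doses are noisy affine transforms of the target's dependency
profile, extreme-low doses are noise, extreme-high doses approach uniform
toxicity, and all doses share a growth-rate-like per-line confound; and
disjoint co-dependency modules whose members share a latent selective
profile in both modalities.

Missing values are injected completely at random at a configurable rate
(default 0) with a single mask mirrored across both modalities, since only
the matching of masks — not their mechanism — matters downstream. All
randomness flows from one root seed through per-component child streams, so
a fixed seed reproduces the bundle bitwise.

What the generator does *not* emulate: reagent-library artifacts corrected
by upstream processors (copy-number cutting bias, miRNA seed effects),
lineage structure in dependencies, and correlated missingness. Passing
tests on this generator therefore demonstrates correctness of the
statistical machinery under its stated assumptions, not robustness to every
artifact of real screens.

## Dependency classification

**Normalized ranks and pan-dependency.** Within each line, genes are ranked
ascending by effect (ties averaged) and divided by the number of observed
genes. Per gene, the 90th percentile of its normalized ranks across lines
summarizes the rank of its most dependent line among the 10% least
dependent — small only when nearly every line is dependent. That summary is
bimodal over genes; `bimodal_minimum()` fits a kernel density (Silverman's
rule, 512-point grid), takes the two highest local maxima as the modes, and
cuts at the density minimum strictly between them. Unimodal input is an
error rather than a guess, directing the caller to supply an explicit
threshold. The percentile (80/90/95) is configurable; on well-separated
data the resulting pan sets are nearly identical.

**Probability of dependency.** Per line, the effect distribution is
decomposed into a null component — kernel density over that line's
non-expressed genes — and a positive component over the dataset's
pan-dependent genes. The posterior that effect `x` is a true dependency is
`pi1 f1(x) / (pi0 f0(x) + pi1 f1(x))`. The mixing weights default to
0.5/0.5 — a symmetric prior that makes the 0.5 decision boundary exactly the
equal-density point — and are configurable. Numerical choices: one shared
bandwidth (Silverman's rule on the pooled, median-centered control
samples); density ratios where both kernel estimates have underflowed are
discarded; beyond the control supports the posterior is pinned to 1 on the
depleted side and 0 on the enriched side; finally an isotonic regression
enforces that the posterior is nonincreasing in the effect. Control genes
are special-cased: a control point inflates its own fitted density at
exactly its own position — negligible in the bulk but dominant in the
tails, which systematically damps control-gene posteriors and, downstream,
deflates the high-variance null threshold — so each control gene's own
posterior is evaluated leave-one-out, with its kernel contribution removed
from its control density (`loo_controls`, on by default). A line is
*dependent* on a gene when its posterior exceeds 0.5 (values exactly at 0.5
count as dependent for the weak rule; a *non-dependency* requires every
line strictly below 0.5).

**Skew-t selectivity.** Strong selectivity is tested by comparing a
Gaussian fit of a gene's profile against an Azzalini-type skew-t
(location `xi`, scale `omega`, slant `alpha`, degrees of freedom `nu`):

LRT = 2 [ ln L(skew-t) - ln L(Gaussian) ].

The Gaussian likelihood has a closed form; the skew-t is maximized by
Nelder--Mead on `(xi, log omega, alpha, log nu)` from method-of-moments
starting values, with strongly slanted extra starts whenever the sample
moments hint at a mixture (|skewness| > 0.25 or excess kurtosis > 0.5) —
those starts exist to escape the near-Gaussian local optimum that
mixture-like samples create. If the default path fails, a two-step ladder
fixes `nu` at each of (2, 5, 10, 25, 50, 100, 250, 500, 1000) in turn,
fits the remaining parameters, then releases `nu`; the first success wins.
Because the Gaussian is a boundary point of the family closure
(`alpha = 0`, `nu -> Inf`), the skew-t log-likelihood is floored at the
Gaussian value, so LRT >= 0 holds exactly. A gene is strongly selective at
LRT >= 100; published descriptions alternate between "> 100" and ">= 100",
so the operator is configurable with ">=" as the default. The slant sign
distinguishes dependency-like left-tail selectivity from right-tail
enrichment.

**High variance.** The variance of the dependency posterior across lines is
compared with its distribution over globally non-expressed (presumed inert)
genes; the cut is the 99th percentile of that null distribution, always
data-derived, never a fixed constant.

**Ordered class assignment.** The five classes are not mutually exclusive,
so a single label is produced by applying rules in a fixed order with
sequential overwrite — later rules take precedence: non-dependent; weakly
selective; strongly selective (LRT); pan-dependent; high-variance; strongly
selective again with the negative-skew condition. The published rule list
names the selectivity rule twice (with and without the skew condition) and
its intended precedence is ambiguous; sequential overwrite is the default
reading — so a gene that is pan-flagged, high-variance-flagged and
negatively skew-selective ends up strongly selective — and a first-match
variant is available behind a flag. Rules 1 and 2 are exhaustive, so the
classes partition the gene set.

**Agreement and high confidence.** Within one modality, two datasets agree
on a gene if it is pan-dependent in both, non-dependent in both, or its
matching-gene correlation ranks first among all cross-dataset pairings.
The high-confidence set is the intersection of agreement across the two
modalities; cross-modality class mapping is reported as a 5x5 contingency
table, optionally restricted to that set.

## Biomarker modeling

Each gene-effect profile is regressed on omics features with random forests
(100 trees, maximum depth 8, at least 5 lines per leaf) under two regimes:
**Related** (features whose subject gene has a prior relationship to the
target, plus always-included confounder and lineage covariates) and
**Unbiased** (top 1000 features by absolute Pearson correlation with the
target). Evaluation uses stratified 5-fold cross-validation — strata are
dependent versus non-dependent lines at the 0.5 posterior (or, absent
posteriors, effect < -0.5), preserving the dependent-line balance per
fold — and accuracy is the Pearson correlation between observed values and
concatenated out-of-fold predictions. The unbiased correlation screen runs
inside each training fold, a leakage-safe placement. Impurity (Gini)
importances are averaged over folds and normalized to sum to one;
importance ties are broken by feature name for determinism.

Marker classes are assigned only to accurate models (r > 0.5) by literal
rules over the top features. Correlation directions are stated here in
gene-effect units (more negative = more dependent): a driver mutation or
fusion must correlate negatively with the effect (mutated lines more
dependent); CYCLOPS requires positive correlation between effect and the
gene's own copy number (copy loss sensitizes); driver copy-number features
use negative correlation (amplification-driven dependency). Published
tabulations of these directions mix the "dependency strength" and "gene
effect" sign conventions between rows; the package resolves all of them in
effect units and documents each rule in `?assign_biomarker_class`.

## Drug--dependency association

Dose-level drug response matrices share a dominant growth-rate-like
component; per dose level, missing values are median-imputed per drug, the
first principal component across cell lines is removed by SVD regression,
and imputed cells are re-masked. Correlations between every (drug, dose)
profile and every eligible gene dependency (at least 3 dependent lines in
either modality) use pairwise-complete observations. Both response and
effect are coded "more negative = more killing", so a matched pair
correlates positively; "best correlated" therefore means most positive
signed correlation by default (an absolute-value mode is available), with
dose ties resolved to the lowest dose. Target recovery reports, per dose
and with each drug represented by its best dose, the fraction of annotated
drug--target pairs whose target ranks in the drug's top-k correlated genes.

## Co-dependency networks

Per modality, the network is the full matrix of pairwise Pearson
correlations between gene-effect profiles. Fusion follows similarity
network fusion with Pearson correlation as the similarity metric: because
the diffusion requires nonnegative affinities, kernels use |r| (the sign is
retained in the raw networks for reporting); full kernels are
row-normalized with diagonal 1/2, sparse kernels keep each row's k = 7
nearest neighbors (k = round(log n) in auto mode) renormalized to row sum
1. Each of exactly 20 iterations — no convergence test — cross-diffuses one
view through the other's sparse kernel, then row-renormalizes and
re-injects the identity (diagonal averaging), the standard regularization
that keeps self-similarity dominant; without it, a view diffused through an
uninformative partner collapses toward a constant matrix and single-view
information is lost. The two nearly converged matrices are averaged and
symmetrized. Prior-relation recovery is scored per query gene by a
one-sided Kolmogorov--Smirnov test on absolute similarity scores and by the
best rank of any related gene; local subnetworks take a query's top-10
co-dependencies with directed edges wherever the target is in the source's
top 10, weighted by global z-scores.

## Pipeline, sizes, and limitations

`run_pipeline()` chains the stages (synth, qc, classify, match, models,
drugs, network) with per-stage manifests keyed by a config hash and the
root seed, making outputs pure functions of (config, seed). The biomarker
stage is opt-in in the default stage list because random-forest
cross-validation dominates runtime.

The package's own validation exercises the full-size generator (400 x 1000)
for pan calling, drug association and network fusion, a 400-line / 500-gene
null plus 200 planted selective profiles for the LRT operating
characteristics, and a 400-line bundle with 50 planted genes per biomarker
mechanism for the marker rules; the acceptance script reproduces the same
quantities at moderately reduced sizes (25 genes per mechanism, 200 null /
100 selective LRT profiles) chosen to keep a complete reproduction fast on
a single core while leaving the conclusions unchanged.

Known limitations: the skew-t optimizer, like any numerical maximizer, does
not guarantee the global optimum (mitigated by multiple starts, the fixed-nu
ladder and the Gaussian floor); kernel-density posteriors are unreliable
when control sets are small (a 20-gene minimum per control set is
enforced); the bimodal threshold requires genuinely bimodal input by
design; and conclusions about real screens are limited by what the
generator emulates, as described above.
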