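---
title: "Chromosome-scale length variation: model, simulator and evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-scale length variation: model, simulator and evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cslv)
library(SummarizedExperiment)
```

## The representation

Genotype-to-phenotype prediction with raw SNP genotypes is a
large-p-small-n problem: millions of markers, thousands of samples.
Chromosome-scale length variation (CSLV) sidesteps it by compressing the
genotype into a handful of dosage summaries. Each SNP-array marker carries
a log R ratio (LRR) — the log of observed over expected total probe
intensity — which behaves as a noisy copy-number proxy: about 0 at the
nominal two copies, positive under gains, negative under losses. Averaging
the LRR over a fixed chromosome segment gives one number per segment per
person, interpretable as the relative amount of chromosomal material in
that segment. With four segments on each of the 22 autosomes the genome
collapses to 88 continuous features, small enough for ordinary tabular
machine learning.

For sample $s$ and segment $g$ with marker set $M_g$,

$$\mathrm{CSLV}(s, g) = \frac{1}{|O_{sg}|} \sum_{j \in O_{sg}} \mathrm{LRR}(s, j),$$

where $O_{sg} \subseteq M_g$ are the markers actually observed. The
estimator is deliberately a fixed-partition mean: no change-point
detection, no CNV calling, no GC-wave correction. Its sampling noise is
$\sigma/\sqrt{|M_g|}$ for per-marker noise $\sigma$, which is what makes
segment-level dosage shifts of a few hundredths detectable from markers
whose individual noise is an order of magnitude larger.

## Segmentation choices

`makeSegments()` partitions each autosome into `k` contiguous segments.
"Quarters" of a chromosome can be read two ways and both are provided:

* `equal_marker_count` (default): maximal-balanced runs of the
  position-sorted markers, the first `m %% k` runs one marker larger.
  Every segment is non-empty and all segment means have near-equal
  variance, which keeps downstream feature scales comparable. Remainder
  markers go to the earlier segments so the rule is deterministic.
* `equal_bp_span`: equal base-pair sub-intervals of the occupied span.
  Closer to a physical notion of a chromosome quarter, but sparse regions
  can leave segments empty (a warning), so it is the option rather than
  the default.

Neither is claimed to replicate any particular published partition
exactly; with array-scale marker densities the two are very similar.
Position ties are broken lexicographically by marker id, making the whole
featurization a pure function of (manifest, k, mode).

Missingness is handled at two explicit levels, because "complete data" can
reasonably be enforced at either granularity: within a segment the mean is
taken over observed markers only, provided at least `minObservedFraction`
(default 0.9) of them are observed — otherwise the entry is `NA`; and
`filterComplete()` then drops any sample with a missing segment value.
Nothing is ever imputed.

## The cohort simulator

Real array cohorts of this kind sit behind controlled access, so the
package ships a generator whose defaults encode the population structure
the featurization assumes; it is first-class, tested code, and every
quantitative claim in the test suite is made against it.

Per marker $j$ (in segment $g$) and sample $i$:

$$\mathrm{LRR}_{ij} = \Delta_{\mathrm{group}(i)}[g] + s[g]\,\mathbb{1}(\mathrm{male}_i)
  + \delta_{\mathrm{cnv}}(i, g) + \varepsilon_{ij},\qquad
  \varepsilon_{ij} \sim N(0, \sigma^2) \;\mathrm{iid}.$$

* **Group shifts** $\Delta$ are phenomenological dosage-shift classes
  ("populations"), not an ancestry model: two groups that differ by a few
  hundredths of an LRR unit on some segments reproduce the situation in
  which group membership is predictable from CSLV features.
* **Sex crosstalk** $s$ is a small male-specific additive shift on a
  subset of autosomal segments (default +0.02 on the first segment of up
  to eight chromosomes). It models the empirical phenomenon that autosomal
  probe intensities are influenced by Y-chromosome presence — plausibly a
  probe-design artifact — which is what lets autosome-only models infer
  sex. The magnitude is a modelling choice, not a measured value.
* **CNV events** hit each (sample, segment) independently with probability
  `cnvRate`; copy numbers 1 and 3 are equiprobable with LRR shifts −0.45
  and +0.30, the conventional attenuated one-copy-loss/gain values for
  array LRR. Both are configurable.
* **Noise.** The default $\sigma = 0.3$ with 400 markers per chromosome
  (100 per segment at k = 4) gives segment means an sd of 0.03,
  qualitatively the dispersion real cohort histograms show. This is a
  realism choice, not a calibration claim.

Height follows
$h_i = \beta_0 + \beta_{\mathrm{sex}}\mathbb{1}(\mathrm{male}_i)
 + \beta_{\mathrm{age}}(a_i - \bar a) + \sum_g \gamma[g]\,T_i[g] + N(0, \sigma_h^2)$,
with $T_i$ the sample's true total segment shift. Defaults
($\beta_0 = 162$ cm, $\beta_{\mathrm{sex}} = 13$ cm,
$\beta_{\mathrm{age}} = -0.06$ cm/yr, $\sigma_h = 6$ cm, ages uniform on
[21, 80]) are ordinary adult-human values; the negative age coefficient
encodes the age-cohort effect (older cohorts grew up with different
nutrition and are shorter on average). $\bar a$ is the midpoint of the age
range, so the intercept does not drift with the sampled ages.

Reproducibility uses one sub-stream per (model component, sample index)
derived from the single cohort seed, so enlarging a cohort never perturbs
earlier samples — a property the tests assert.

**What the simulator does not emulate:** linkage disequilibrium, allele
frequencies and real ancestry structure, GC waves and batch effects in
LRR, realistic BAF (written as a constant 0.5 placeholder), and X/Y data.
Tests passing against it therefore demonstrate that the pipeline recovers
segment-level dosage structure it was built for — not that any particular
accuracy will transfer to a real cohort.

## The analytic oracle

For two groups differing only in $\Delta$ (no CNV, no crosstalk), CSLV
features are equal-covariance Gaussians and the Bayes-optimal linear
discriminant has

$$\mathrm{AUC} = \Phi\!\left(\frac{D}{\sqrt 2}\right),\qquad
  D^2 = \sum_g \left(\frac{\Delta_1[g] - \Delta_2[g]}{\sigma/\sqrt{m_g}}\right)^2.$$

`expectedPairAUC()` implements this closed form and refuses configurations
(CNV or crosstalk active) where it is invalid. The acceptance suite
simulates cohorts of 2,000 at expected AUCs 0.760 and 0.943 and checks the
empirical repeated-holdout mean lands within ±0.02, with a null
configuration bracketed in [0.45, 0.55].

## The evaluation harness

`modelSearch()` emulates an AutoML-style search with a deterministic trial
budget rather than a wall clock (wall-clock budgets are
hardware-dependent and unreproducible): a fixed grid over four families —
regularized linear/logistic models, gradient-boosted trees, random
forests, and a small feed-forward network — consumed round-robin up to
`trialBudget` candidates (default 24), each scored by pooled out-of-fold
cross-validation (default 10 folds). Two stacked ensembles (all models;
best of each family) use a ridge meta-learner with non-negative weights on
out-of-fold predictions — non-negativity means the ensemble can in
principle reproduce any single base model, which is why ensembles
empirically top the leaderboard or sit near the top. Grids are fixed in
code, never adapted to results, so a search is a pure function of (table,
spec).

Other conventions worth stating:

* **AUC** is computed by midranks (Mann–Whitney with ties half-credited);
  the reported value equals the trapezoidal area of the returned ROC
  points to machine precision, and the tests verify both against
  exhaustive pair counting.
* **Splits.** `splitCounts()` floors fractional products with a 1e-9
  guard so exact products (161,820 × 0.8 = 129,456) stay exact under
  floating point. Degenerate holdout splits (single-class test set) are
  redrawn with a message, at most 10 times.
* **Repeated holdout** reports per-repeat AUCs plus mean and sd across
  repeats (the sd across repeated random splits, not across CV folds —
  both protocols exist and the harness keeps them separate:
  cross-validation lives in `modelSearch()`, repeated splits in
  `repeatedHoldout()`).
* **Grouped-mean curve.** Test samples are ranked by prediction and cut
  into `nGroups` contiguous groups, sizes differing by at most one with
  larger groups first; 32,364 samples in 50 groups give 14 groups of 648
  and 36 of 647. Ties in predictions are broken by stable input order.
* **Importance** is permutation importance (mean metric drop over
  repeated within-column shuffles), the model-agnostic analog of a
  variable-importance display; per-observation attribution methods such
  as SHAP are out of scope and permutation importance is stated as the
  substitute wherever it is reported.
* **Height task contract.** Regression uses age plus all CSLV columns and
  nothing else — sex and group label are withheld — and removes anyone
  under 21 so only fully grown people enter. The interesting consequence,
  reproduced in the acceptance suite, is that the model still recovers sex
  through the crosstalk-carrying segments: the 50-group curve shows two
  height levels whose gap dwarfs the within-level steps. The two-level
  check labels each group by its majority sex and requires the gap between
  the female-majority and male-majority level means to exceed 4 × the
  median absolute step between same-level neighbouring groups. (A largest-
  single-jump statistic would be the obvious alternative, but the sex
  transition smears across adjacent groups whenever predictions mix sexes
  near the boundary, so the single-jump version is unstable.)

## Problem sizes

The shipped tests and the acceptance script run cohorts of 1,000–10,000
samples with 400 markers per chromosome (up to 8,800 markers over all 22
autosomes), model searches with 3–10 folds and budgets of 4–8 candidates,
and 50-group curves on test sets of ~800. These sizes were chosen so the
statistical claims (CLT recovery bounds, ±0.02 AUC calibration,
two-level curve structure) are comfortably resolvable by simulation while
a full run stays in the minutes range on one CPU; the same code scales to
cohort sizes in the 10^5 range simply by raising `nSamples`.

## Known limitations

* CSLV is intentionally lossy: it cannot localize a signal below segment
  resolution, and a duplication and deletion in the same segment cancel.
* The fixed partition means segment boundaries are arbitrary with respect
  to real CNV boundaries; the method trades interpretability for
  compactness.
* The simulator's group structure is additive and Gaussian; real
  population structure in LRR space need not be either.
* `equal_bp_span` segmentation can produce empty segments on sparse
  manifests, which then propagate missing features and empty samples under
  complete-case filtering — by design, but easy to trip over.
* LRR is treated as an opaque dimensionless log ratio; the package never
  re-bases it (log2 vs log10) and never re-normalizes it.
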