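# cslv — chromosome-scale length variation features from SNP-array log R ratios

Genotype-to-phenotype prediction from raw SNP genotypes is a
large-p-small-n problem: a genotype is ~10^6 markers, a cohort rarely more
than ~10^5 people. `cslv` implements a compact alternative representation
of the genome. Each array marker's **log R ratio** (LRR) — the log of
observed over expected total probe intensity — is a noisy copy-number
proxy (0 ≈ two copies, positive ≈ gain, negative ≈ loss). Averaging LRR
over fixed segments of each autosome gives the **chromosome-scale length
variation** (CSLV) of that segment:

```
CSLV(s, g) = mean over observed markers j in segment g of LRR(s, j)
```

With four segments per autosome over chromosomes 1–22 a genome becomes 88
continuous features (`chr1_1 … chr22_4`; `chr6_2` is the second segment of
chromosome 6), which net gains and losses of chromosomal material imprint
on directly — small enough for ordinary tabular machine learning, at the
price of losing all sub-segment localization.

The package provides, Bioconductor-style (S4 classes over
`SummarizedExperiment`/`GRanges`):

* **IO** — long ("Final-Report"-like) and wide LRR readers with
  chromosome-label normalization and autosome-only filtering
  (`readLRRLong`, `readLRRWide`), plus deterministic, exact-round-trip
  writers for feature, phenotype and cohort files.
* **Featurization** — `makeSegments` (equal-marker-count or equal-bp-span
  partitions), `computeCSLV` (mean over observed markers, never imputing),
  `filterComplete` (sample-level complete cases), `segmentHistogram`.
* **A cohort simulator** — `simConfig`/`simulateCohort` draw cohorts with
  group-level dosage shifts, a male-specific autosomal "sex crosstalk"
  shift, sporadic CNVs, and a height model with sex, age-cohort and
  heritable dosage effects; ground truth is returned alongside.
  `expectedPairAUC` gives the closed-form Bayes-optimal AUC for two-group
  contrasts, the oracle the harness is calibrated against.
* **An evaluation harness** — `modelSearch` (budgeted AutoML-style search
  over glmnet / xgboost / ranger / nnet with two stacked ensembles and a
  leaderboard), `repeatedHoldout` (AUC mean ± sd over random 80/20
  splits), `aucROC` (Mann–Whitney ties-half AUC with exact trapezoid
  identity), `splitCounts`, `groupedMeanCurve` (ranked equal-group curve
  for regression), `permutationImportance`.

## Worked example

Two simulated populations differ by a +0.012 LRR shift on the first
segment of chromosomes 1–10 — a dosage signature far below per-marker
noise (sd 0.2) but visible in segment means (sd 0.2/√100 = 0.02):

```r
library(cslv)

labels <- sprintf("chr%d_%d", rep(1:22, each = 4), 1:4)
delta <- setNames(rep(0, 88), labels)
delta[sprintf("chr%d_1", 1:10)] <- 0.012
cfg <- simConfig(
  nSamples = 1500, markersPerChromosome = 400, chromosomes = 1:22, k = 4,
  lrrNoiseSD = 0.2, cnvRate = 0, sexCrosstalk = FALSE,
  groups = list(list(label = "A", proportion = 0.5, delta = delta),
                list(label = "B", proportion = 0.5)),
  seed = 42)
cohort <- simulateCohort(cfg)
features <- filterComplete(computeCSLV(lrrData(cohort), segmentScheme(cohort)))
features
#> class: CSLVTable
#> dim: 88 1500
#> assays(1): cslv
#> rownames(88): chr1_1 chr1_2 ... chr22_3 chr22_4

spec <- taskSpec("binary_classification", positive = "A", negative = "B",
                 labelColumn = "group_label", cvFolds = 5, trialBudget = 8,
                 seed = 1)
task <- buildTask(features, phenotypes(cohort), spec)

expectedPairAUC(cfg, c("A", "B"))      # Bayes-optimal AUC for this contrast
#> [1] 0.9101438

repeatedHoldout(task, modelRecipe("glm"), spec)
#> RepeatedAuc over 5 splits: mean AUC = 0.8683, sd = 0.0076

head(leaderboard(modelSearch(task, spec)), 5)
#>   rank                     model_id   family    metric
#> 1    1 StackedEnsemble_BestOfFamily ensemble 0.8922526
#> 2    2    StackedEnsemble_AllModels ensemble 0.8915948
#> 3    3                        GLM_2      glm 0.8851176
#> 4    4                        GLM_1      glm 0.8847762
#> 5    5                        GBM_1      gbm 0.8845949
```

Reading the numbers: the closed form says a perfect linear discriminant on
these features reaches AUC 0.910; a logistic model fitted on 1,200
training samples with 88 features gets 0.868 ± 0.008 over five random
splits, and the cross-validated search's stacked ensembles close part of
the remaining gap (0.892). Empirical AUCs approach the oracle from below
as the cohort grows — at n = 2,000 with fewer informative segments the
calibration tests require agreement within ±0.02.

A thin CLI over the same functions is installed at `exec/cslv.R`
(subcommands `featurize`, `simulate`, `classify`, `regress`).

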