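---
title: "Heterogeneity-aware genetic risk prediction with likelihood-ratio ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity-aware genetic risk prediction with likelihood-ratio ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clefthet)
```

## The problem

Oral clefts — and many other complex diseases — present as a family of
clinically refined sub-phenotypes: left, right and bilateral cleft lip,
cleft lip with palate, soft and hard cleft palate only. Sub-phenotypes with
similar clinical appearance can have partly distinct genetic etiologies.
This puts risk modelling in a bind. Pool everything into one case group and
the predictors specific to one etiology are diluted by cases from the
others; model every sub-phenotype separately and each model starves on a
tiny case count (a hundred-odd cases against thousands of controls). The
analysis implemented here lets the data arbitrate: sub-phenotypes are
merged step by step, most-genetically-similar pair first, and
cross-validation decides how far the merging should go.

## The risk score: saturated genotype-combination likelihood ratios

For a set of $k$ selected SNPs with additive genotype coding
$g_j \in \{0,1,2\}$, the risk score of an individual with genotype
combination $c = (g_1, \dots, g_k)$ is the nonparametric likelihood ratio

$$\mathrm{LR}(c) \;=\; \frac{\hat P(c \mid \text{case})}{\hat P(c \mid \text{control})},$$

estimated over the full joint table of $3^k$ combinations with a
pseudo-count $\alpha$ added to every cell:

$$\widehat{\mathrm{LR}}(c) = \frac{(n^{\text{case}}_c + \alpha)/(N^{\text{case}} + 3^k\alpha)}
{(n^{\text{ctrl}}_c + \alpha)/(N^{\text{ctrl}} + 3^k\alpha)}.$$

Because the table is saturated, no mode of inheritance is assumed and
interactions of any order among the selected SNPs are captured
automatically; by the Neyman–Pearson lemma, ranking by the true LR
maximises the ROC curve at every operating point, and the test suite
verifies by exhaustive enumeration that no ordering of genotype cells beats
the empirical LR ranking on small instances. The pseudo-count (default
$\alpha = 0.5$, the Jeffreys choice) guarantees positive finite scores for
all cells, including combinations unseen in training. The table size is
capped at $3^6$ cells: beyond six SNPs a saturated table on candidate-panel
sample sizes is pure noise, and the model refuses rather than degrade
silently.

Missing genotype calls are imputed to the per-variant modal genotype of the
training samples; the imputation map is stored in the model and reused when
scoring new samples. Imputation is computed once per forward-selection call
(on the samples provided to it); outer cross-validation folds therefore get
their own imputation, while inner selection folds share their parent's —
a deliberate trade of a negligible optimism against a several-fold cost in
the inner loop.

## Forward selection

SNPs enter a group's model greedily: at each step, every remaining
candidate is evaluated by the AUC of the joint LR model including it, and
the best is added if it improves on the current selection AUC by at least
`min_auc_gain` (default 0.005). The selection AUC is, by default, the mean
held-out AUC over 5 stratified inner folds (`inner_folds = 5`); with
`inner_folds = 0` it is the apparent AUC, which is monotone nondecreasing
in model size for a saturated table, so stopping then rests on the gain
threshold and `max_snps` (default 5). Ties break to the lexicographically
smallest rsid — reproducibility over optimality. AUCs are computed with the
Mann–Whitney estimator (ties half-credited), and confidence intervals with
the DeLong structural-components variance.

A known limitation of this stopping rule: when the candidate panel is
large, the *maximum* of the inner-CV AUCs over ~150 null candidates sits
two to three AUC standard errors above 0.5, which exceeds any gain
threshold small enough to admit genuine 2–3-SNP models. Null data therefore
usually produce a non-empty model rather than an empty one. This is a
selection-optimism property of any argmax-with-threshold rule, not an
estimation defect; what matters — and what the tests assert — is that
models selected on null data carry no held-out signal (held-out global ROC
calibrated at 0.5 to within 0.02), and the empty-model path is still
reachable (degenerate data return a constant score with a warning).

## Genetic similarity and agglomerative merging

The similarity between case groups $i$ and $j$ is symmetric cross-applied
discrimination:

$$\mathrm{sim}(i,j) = \tfrac12\left[\mathrm{AUC}\!\left(M_i;\,\text{cases}_j\,\text{vs controls}\right) + \mathrm{AUC}\!\left(M_j;\,\text{cases}_i\,\text{vs controls}\right)\right],$$

where $M_i$ is group $i$'s fitted model. If the groups share etiology, each
model discriminates the other's cases nearly as well as its own
(similarity near the groups' own AUCs); if etiologies are disjoint, the
cross-AUCs sit at 0.5. Empty models score everyone identically, so their
cross-similarities are exactly 0.5. Among the definitions compatible with
"genetic similarity" (predictor-set overlap, likelihood-based distances),
cross-applied AUC was chosen because it measures exactly the quantity the
merge decision cares about — whether one group's risk model transfers to
the other — and it is computable from components the pipeline already has.
Alternatives can be swapped in at the `pairwise_similarity()` surface.

Merging is greedy: fit a forward-selected model per group, merge the most
similar pair, refit the merged group *from scratch* on the pooled cases
(pooling can reveal different predictors, so unioning the two SNP lists
would be wrong), and repeat until one group remains. Ties on similarity go
to the pair with the larger pooled case count (the power motivation of
merging), then lexicographic order. Models of untouched groups are carried
over unchanged between levels.

## Choosing the number of groups

The merge path is scored by the **global ROC statistic**: the
case-count-weighted mean of the per-group one-versus-controls AUCs. Case
weighting rewards accuracy on the groups where most cases live and thereby
encodes the trade-off the merging is meant to optimise (an unweighted mean
is available). The number of groups is chosen by K-fold cross-validation
(default $K = 5$, stratified by label so every sub-phenotype and the
controls appear in every fold): the merge path is built on each training
set, every level is evaluated on the held-out fold using the training
models and the training merge order — held-out samples never influence
which groups merge — and the group count with the highest mean held-out
global ROC wins, ties resolved toward fewer groups. The final models are
then refit on all samples, stopping the merge path at the selected count.

## The synthetic-data generator

Because the motivating consortium genotypes are controlled-access, the
package ships a generator that emulates their structure: a shared control
pool drawn at Hardy–Weinberg equilibrium from per-SNP counted-allele
frequencies; case sub-phenotypes with the published unbalanced count
profile (223, 172, 244, 114, 485, 271, 336 after filtering, scalable);
~148 candidate SNPs of which a few are causal; latent etiology groups that
partition the sub-phenotypes, each with its own causal set, optionally
sharing SNPs through a common causal set; multiplicative genotype relative
risks on a baseline risk (default 0.01), with optional two-locus
interaction factors applied when both loci carry a risk allele. Case
genotypes at the risk SNPs follow the population distribution weighted by
the disease probability; when the risk-SNP set is small (≤ 8 SNPs) this
conditional distribution is enumerated exactly and sampled directly, which
is distributionally identical to rejection sampling and exactly matches the
closed-form oracle `expected_auc()` used in the tests. Non-causal SNPs are
identically distributed in cases and controls by construction. Everything
is deterministic given the config seed.

What the generator does *not* emulate: linkage disequilibrium between panel
SNPs (candidate panels are treated as independent loci), population
structure, sex-specific effects (the real data show a marked sex imbalance
across sub-phenotypes), and the case-parent trio design — the published
analysis reports a flat control count without a construction recipe, so an
unmatched case-control pool is modelled and trio-aware pseudo-controls are
out of scope. Passing recovery tests on these simulations therefore shows
the machinery is correct and calibrated under the stated model, not that
real cleft data are this clean: real panels have LD (selection then picks
tagging proxies), confounding, and smaller effect sizes.

## Numerical and design choices

- **AUC**: Mann–Whitney with half-credit ties, computed on midranks; inside
  the selection loop AUCs are computed directly from genotype-cell counts,
  which is exact and orders of magnitude faster than per-sample ranking.
- **CI**: DeLong variance with a normal approximation, clamped to [0, 1];
  degenerate score sets collapse the interval instead of failing. The CI
  method is cross-checked against an independent reference implementation
  in the test suite.
- **Filtering**: sub-phenotypes below `min_cases_per_subtype` (default 50,
  sitting between the excluded n = 30 and retained n = 114 of the
  motivating data, configurable) and explicitly excluded labels (e.g. an
  "Unknown" category) are dropped; controls never are.
- **Determinism**: every stochastic step (simulation, fold assignment,
  inner CV) is seeded; identical configuration and seed give byte-identical
  artifacts. Report JSON is written with 17 significant digits so scores
  round-trip losslessly.
- **Problem sizes**: the validation experiments use 50 replicates of
  desk-scale designs (e.g. 4 sub-phenotypes × 300 cases, 2 000 controls,
  148 SNPs for the heterogeneity-recovery study; 150 cases per subtype and
  1 000 controls for the null calibration; 1 000 replicates for CI
  coverage), with apparent-AUC selection (`inner_folds = 0`) inside the
  replicate loops — the outer cross-validation already guards the
  group-count decision against overfitting, and the package default of
  inner-CV selection is kept for single-dataset analyses, as in the
  `analysis/` scripts.
- **Causal architecture in the recovery studies**: three causal SNPs per
  etiology at GRR 2, MAF 0.3 — per-SNP AUC ≈ 0.62, three-SNP models ≈ 0.70,
  i.e. effect sizes at the optimistic end of what candidate-gene panels
  deliver, chosen so that recovery failures indicate algorithmic faults
  rather than power limits.

## Known limitations

- Reported per-group AUCs of the final full-data fit are apparent
  (training) AUCs with DeLong CIs; the cross-validated global ROC curve is
  the honest generalisation estimate and both are written to the report.
- The greedy merge is not a global partition optimiser; with weak signal it
  can lock in an early wrong merge.
- The stopping rule's selection optimism (above) means model *size* should
  not be over-interpreted on weak-signal data, even though held-out
  performance remains calibrated.
- Likelihood-ratio tables are saturated; with more than ~5 SNPs or very
  rare genotypes the per-cell estimates are noisy and inner-CV selection
  becomes essential.
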