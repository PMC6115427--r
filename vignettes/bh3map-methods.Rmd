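---
title: "Methods: dependency scoring, synergy, biomarkers and screen analysis in bh3map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dependency scoring, synergy, biomarkers and screen analysis in bh3map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bh3map)
```

## The analytical problem

Solid tumors evade apoptosis through a redundant set of anti-apoptotic
BCL-2 family proteins (BCL-2, BCL-XL, MCL-1, and the less-studied
BCL-w and BFL-1). Selective BH3-mimetic inhibitors exist for the first
three (ABT-199/venetoclax for BCL-2, WEHI-539 for BCL-XL, A-1210477
for MCL-1), which makes it possible to ask, cell line by cell line,
*which* anti-apoptotic protein a tumor depends on for survival — and
whether that dependency is predictable from gene expression.

`bh3map` implements the full analysis chain for a combinatorial
single-concentration BH3-mimetic viability panel: eight conditions
(vehicle, three single agents, three pairs, and the triple
combination) measured by a luminescence viability assay in replicate
wells. Because the raw screen data this design comes from are not
publicly deposited, the package pairs every analysis stage with a
seeded synthetic-data generator that plants known effects, so each
stage is validated by parameter recovery rather than by re-deriving
any published table.

## Dependency scores

For one cell line under one condition, the dependency score is

$$\mathrm{score} = 100\left[1 - \frac{\overline{S}_{\mathrm{treated}}}{\overline{S}_{\mathrm{vehicle}}}\right]$$

clamped to $[0, 99]$: replicates are averaged *before* the ratio (the
mean-of-replicates convention, not the mean of per-replicate ratios),
0 means no apparent viability loss, and the cap at 99 keeps the 0–1
rescaled scores strictly below 1. The score is invariant to the
arbitrary luminescence scale and monotone in treated signal, both of
which are property-tested.

Sensitivity classes use strict cutoffs: *sensitive* (> 50 points),
*dependent* (> 25), *non-responding* (< 20) and *innately resistant*
(< 10). The 20–25 band has no named class in the source convention;
`classify_label()` labels it `"intermediate"` explicitly rather than
silently absorbing it into a neighbour.

## Bliss synergy

Synergy for the BCL-XL + MCL-1 combination is computed on the 0–1
dependence scale (scores divided by 100). Two variants are provided:

* `bliss_synergy_printed(x, m, c)` $= (1-x)(1-m) - c$, the formula as
  printed in the source convention;
* `bliss_synergy_excess(x, m, c)` $= c - \big[1 - (1-x)(1-m)\big]$,
  the canonical Bliss excess: observed combined loss minus the loss
  expected if the two drugs acted independently (combined survival =
  product of single-agent survivals).

The printed variant assigns $+1$ to a line that responds to nothing,
which is incompatible with using high synergy scores to define a
*synergistic co-dependent* group alongside an *insensitive* group, and
with a reported score range topping out near the maximal combination
response. We therefore implement the printed formula verbatim for
fidelity but use the excess for grouping and correlations; the two are
algebraically linked by
$\mathrm{printed} + \mathrm{excess} = 2(1-x)(1-m) - 1$, which is
regression-tested. The excess is exactly 0 on Bliss-additive triples.

Group assignment: *single-dependent* if either single-agent dependence
exceeds 0.25 (the 25-point cutoff); otherwise *synergistic
co-dependent* if the synergy exceeds `synergy_cutoff` **and** the
combination passes the `dependent>25` cutoff; otherwise *insensitive*.
No synergy cutoff is stated in the source convention; the default of
0.25 on the excess scale mirrors the single-agent cutoff and is a
configurable parameter, not a fitted constant.

## Linear models and predictor comparison

`fit_linear()` fits $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 I)$ by ordinary least squares (through
`stats::lm()` after explicit intercept and rank checks), and
`r_squared()` reports $R^2 = 1 - SS_{\rm res}/SS_{\rm tot}$ with
$SS_{\rm tot}$ about the mean response. `compare_predictors()` fits,
per dependency phenotype, a tissue-only and a mutation-only model and
compares their $R^2$. We deliberately fit *separate* models per
predictor set: the comparison is about which data type explains the
response better, and a joint model's partial contributions would
answer a different question. Mutation status is a single binary state
per gene (point mutation, amplification or deletion all count as
"mutant"). A gene mutated in all or no shared lines is dropped as
uninformative.

## The sliding-scale threshold finder

`find_threshold()` searches for the expression cutpoint that best
segregates high- from low-score lines. Candidate thresholds are the
midpoints between consecutive *distinct* sorted expression values
(ties collapse to one candidate); a candidate is admissible when both
sides retain at least `min_group_size` lines (default 3 — the source
convention states no floor, so this default is prominent and
configurable). Each admissible split is scored with a two-sample
t-test (pooled-variance Student by default, Welch by flag) and the
split with the smallest p-value wins. Ties on p break by larger
between-group mean difference, then by lower threshold, so results are
deterministic. The scan is computed with cumulative sums in $O(n)$
per pass after sorting, which makes permutation adjustment cheap.

Two numerical edge cases are defined rather than left to float
behaviour: a split with zero within-group variance on both sides has
$p = 0$ if the means differ (perfect separation) and $p = 1$ if they
coincide; a cohort with all-equal scores therefore returns $p = 1$
everywhere and the lowest admissible threshold.

Because the winning p-value is a minimum over many correlated tests,
it is selection-biased and *not* uniform under the null — the suite
demonstrates this. `n_perm > 0` adds a permutation-adjusted p-value
(proportion of score permutations whose best split beats the observed
one, with the +1 correction) whose null rejection rate at 0.05 is
calibrated, verified over 500 simulated null cohorts.

`validate_threshold()` applies a *fixed* threshold (never re-fit) to
an independent cohort, e.g. splitting external lines at an expression
cutpoint and t-testing their log2 IC50 values.

## EMT signatures and tissue averages

Signature scores are plain sums of log2 expression over fixed marker
lists — epithelial: MUC1, CDH1, EPCAM, CLDN3; mesenchymal: SNAI1,
SNAI2, TWIST1, TWIST2, VIM, CDH2. Protein-style aliases (SNAIL, SLUG,
E-cadherin, N-cadherin) resolve to these symbols at read time. Absent
member genes are recorded and excluded, never imputed: the sum is over
a fixed small list and imputation would fabricate signal; the carried
gene count lets cross-matrix comparisons restrict to complete cases.
Scores are not z-scored by default (the definition sums raw values);
`standardize = TRUE` exists for cross-dataset use. Tissue averages
weight lines equally — no replicate-quality weighting is defined
anywhere, so none is invented.

## Outlier analysis

Per line, the dependency delta is the percentage difference from its
tissue's mean score, `100 * (score − tissue mean)/tissue mean`,
defined as 0 when both are 0. Expression deltas are computed the same
way but on the linear scale ($2^{\log_2 x}$) — a "percentage
difference" of log2 values would depend on the log base and have no
biological reading. A concordance flag marks lines whose dependency
and driver-gene deltas deviate in the direction an association table
predicts. Singleton tissues have no meaningful average and are
skipped with a message.

## CRISPR screen scoring

Counts are normalized to reads per million with a pseudocount
(default 1; the normalization is not stated in the source convention,
so the minimal standard for pooled screens is used and exposed as a
parameter). Per-sgRNA log2 fold changes are
`log2(mean treated RPM) − log2(mean DMSO RPM)` — replicates are
averaged on the RPM scale *before* the log, which stabilizes zeros;
the suite pins this collapse order against the mean-of-logs
alternative so it cannot drift silently. Each gene's depletion metric
(DM) is its *three-score*: the mean of its 3 most-depleted sgRNA fold
changes ("best" is read as most depleted — the screen is negative
selection and sensitizers drop out of the treated arm). DM stays on
the log2 scale with no further transformation. Genes rank ascending.

Hit calling is a package convention (the original analysis highlighted
genes by inspection): the 50 control sgRNAs are chunked
deterministically, in sorted id order, into pseudo-genes of the modal
library size; a gene is a hit when its DM falls below the 5th
percentile of the control pseudo-gene DM distribution, and a z-score
against that distribution is reported alongside.

Note the three-score of a true-null gene is *negatively biased* (it is
a mean of lower order statistics), by about $0.55\,\sigma_{\rm LFC}$.
At the simulator's default coverage and dispersion this bias is
≈ −0.08 log2 units — visible in every null screen and harmless for
ranking, since it shifts all genes equally.

## The synthetic-data generator

`simulate_screen()` generates every pipeline input from one seed, with
all planted parameters recorded in a `truth` slot. What it emulates,
and the defaults chosen where no value is stated anywhere:

* **Cohort**: 78 lines over 10 tumor types in triplicate, matching
  the profiled design. Untreated signals are log-normal around $10^6$
  arbitrary units (a realistic luminescence scale; it cancels in
  scoring).
* **Single-agent dependence**: per-tissue base rates (leukemia lines
  lean BCL-2/MCL-1, solid lines carry modest baselines) plus planted
  rules. The default rules encode the biomarker logic under study:
  NOXA (PMAIP1) expression above 10 log2 units adds 45 points of
  BCL-XL dependence; BCL-XL (BCL2L1) expression below 7 adds 45
  points of MCL-1 dependence.
* **Combinations**: Bliss-independent composition (combined survival
  = product of single-agent survivals). No generative model for
  combinations is stated anywhere — only the scoring formula — and
  this choice makes the synergy scorer's null exactly testable.
  Epithelial-classed lines additionally gain a planted synergy of
  0.30 on the two conditions co-inhibiting BCL-XL and MCL-1;
  mesenchymal-classed lines gain 0.15 of BCL-XL dependence. These
  couplings reproduce the qualitative EMT structure: synergy
  anti-correlates with the mesenchymal state, BCL-XL dependence
  correlates with it.
* **Noise**: replicate signals are multiplied by
  $1 + N(0, \sigma)$ with $\sigma = 0.05$ (5% of signal), a typical
  well-to-well CV for luminescence viability assays; no replicate
  noise magnitude is reported anywhere, so this default is easy to
  override (`noise_sd_viability`). At $\sigma = 0$ recomputed scores
  equal $100\times$ the planted losses exactly, which anchors the
  round-trip tests.
* **Screen**: 398 genes × 5 sgRNAs + 50 controls, duplicate
  conditions, negative-binomial counts (pooled screens are
  overdispersed; Poisson would understate the noise) with dispersion
  0.01 and log-normal baselines around 1000 reads — the 1000×
  coverage the screening protocol maintains. Sensitizers (defaults:
  BCL2L2/BCL-w and BCL2A1/BFL-1) receive −2 log2 on 3 of their 5
  sgRNAs. `dispersion = 0` is the deterministic noiseless limit.

What the generator does **not** emulate: batch and plate-position
effects, dose–response (the panel is single-concentration by design),
mutation–expression correlation structure, tissue-specific expression
covariance, or sgRNA efficacy heterogeneity beyond the planted 3-of-5
pattern. Passing recovery tests therefore demonstrate that the
estimators recover what they claim *under the stated statistical
model*, not that real screens are free of these complications.

## Problem sizes used in the validation suite

The test suite and the acceptance script run parameter-recovery
experiments at the study's own scale: 50-seed repetitions for
threshold recovery (60-line cohorts, 60-point effects, score noise
s.d. 10), predictor comparison (30-line three-tissue cohorts),
EMT sign structure (full 78-line cohorts) and screen recovery (full
398-gene screens), plus 500 null cohorts for the permutation-p
calibration. Exhaustive oracle equivalence for the threshold finder
is checked for all cohort sizes up to 12, where brute-force
enumeration of every admissible split is feasible.

## Known limitations

* The printed-formula/excess discrepancy in the synergy definition is
  resolved by a documented choice, not by knowing which variant
  produced the original figures; both numbers are always emitted.
* The threshold finder's raw p-value is intentionally reported as the
  minimum (that is the method); users comparing thresholds across
  many genes should use the permutation adjustment or treat the raw
  values as ranking scores only.
* Dependency scores saturate at 99, so planted effects pushing lines
  past complete kill compress; recovery tests use effect sizes within
  the dynamic range.
* The hit-calling rule for the screen rests on only 10 control
  pseudo-genes at the default library size; with fewer than ~10
  controls the 5th-percentile cutoff is unstable, and `score_screen`
  reports `NA` hits when fewer than two pseudo-genes can be formed.
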