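---
title: "Qualitative interaction trees: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative interaction trees: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quintree)
```

## The scientific problem

Average treatment effects hide heterogeneity. In a two-arm randomized trial
that is null overall, an active medication may still help one subgroup of
participants while another subgroup would have fared better on placebo. A
qualitative interaction tree (QUINT) searches the baseline covariate space
for exactly this pattern: it recursively partitions participants into
leaves with homogeneous treatment effects and labels every leaf *treatment
responder* (P1: active beats placebo), *iatrogenic responder* (P2: placebo
beats active) or *nonresponder* (P3). The defining feature, compared with
ordinary regression trees, is that the split criterion targets the
*within-leaf treatment effect*, not the outcome level, and that a fit is
only declared when the interaction is *qualitative* — effects of opposite
sign must coexist.

`quintree` implements this analysis for drinking outcomes derived from
daily timeline-followback (TLFB) records, together with the missing-data
handling such secondary analyses require, a bootstrap validation of the
effect-size spread, and a synthetic trial generator with planted ground
truth.

## Outcomes from daily drinking records

A heavy drinking day (HDD) is a day with at least 4 standard drinks for
females or 5 for males (`is_heavy_day()`, thresholds inclusive). With day 0
the day of randomization, `derive_outcomes()` computes per participant:

* `phdd_base` — proportion of heavy days in the 28-day baseline window
  (days −28..−1 by default);
* `phdd_maint` — proportion of heavy days among *observed* maintenance
  days; the maintenance phase defaults to weeks 2–25, days 8..175;
* `raw_change` = (phdd_base − phdd_maint) × 28, in days per 28-day period;
* `prop_change` = (phdd_base − phdd_maint) / phdd_base, unitless.

Two decisions deserve emphasis. First, unobserved maintenance days are
excluded from the denominator rather than treated as abstinent: zero-filling
would fabricate abstinence for participants who stopped reporting, and a
participant with no observed maintenance days has a *missing* outcome set.
Second, the raw change is expressed per 28-day period rather than as a
count over the whole 168-day phase, so that its magnitude is commensurate
with the baseline window; this scaling is an assumption of the
implementation and is configurable by rescaling the column. `prop_change`
is undefined when `phdd_base` is 0 (the record is retained, `raw_change` is
still computed); trial inclusion criteria normally make this case
impossible, and the synthetic generator enforces at least 4 baseline heavy
days.

## Missing-data policy

The pipeline distinguishes three kinds of missingness.

* **Predictor items** ("Refuse to Respond" and similar codes, mapped to
  `NA` at load time by the schema): filled by deterministic
  chained-regression imputation (`impute_predictors()`). Missing cells are
  initialized at column medians; for a fixed number of sweeps (default 10)
  each incomplete predictor is regressed by OLS on all others over its
  originally observed rows and its missing cells are replaced by fitted
  values, snapped to the nearest legal value for ordinal/binary features.
  Observed cells are never altered; the same seed gives identical output.
  Ten sweeps are far past the fixed point for the battery sizes involved;
  the simplest deterministic chained scheme was chosen because no specific
  algorithm is dictated by the analysis being emulated, and single-dataset
  (not multiple) imputation matches the single-model results reported in
  such analyses.
* **High-"Not Applicable" items**: an item whose trial-wide missing
  fraction reaches the exclusion threshold (default 0.10) is dropped from
  its questionnaire scale for the whole trial (`excluded_items()`,
  `score_scales()`); scores are sums of the retained, observed-plus-imputed
  items. A threshold of 1 or more disables the policy. The rule is
  inclusive (`fraction >= threshold`) so that an item missing for exactly
  10% of participants is excluded at the default threshold.
* **Weekly compliance**: missing entries are zeroed
  (`handle_compliance()`) — medication was dispensed at weekly visits, so a
  missed visit means no dispensation, not an unknown dose.
* **Outcomes**: participants missing the entire maintenance phase are
  handled by one of two strategies (`resolve_missing_outcomes()`):
  `"exclude"` drops them; `"impute"` fills each outcome by a single OLS
  regression on the (complete, already imputed) predictors. Both
  strategies are first-class so their downstream optimism can be compared;
  which one shows less bias is a property of the data, not of the package.

## The partitioning criterion

Leaves are summarized by `leaf_effect()`: per-arm sizes, means and SDs, the
mean difference `delta = mean_p − mean_t` (placebo minus active, the
convention of published per-leaf tables), the pooled SD
`s_pool² = ((n_p−1)sd_p² + (n_t−1)sd_t²)/(n_p+n_t−2)`, the pooled-variance
standard error `se = s_pool·√(1/n_p + 1/n_t)`, and Cohen's
`d = (mean_t − mean_p)/s_pool` with the normal-theory interval
`d ± 1.96·se/s_pool`. Positive `d` means the active arm reduces drinking
more. The pooled (not Welch) SE was adopted because it reproduces the
printed SEs of the published per-leaf tables to printed precision; `d` is
uncorrected for small samples by default, with the Hedges factor available
behind a flag.

A class assignment of the current leaves is scored by

$$C = a_1\left[\log(1+D_1) + \log(1+D_2)\right] +
      a_2\left[\log(N_1/N) + \log(N_2/N)\right]$$

with $D_1$ the size-weighted mean $d$ over P1 leaves, $D_2$ the
size-weighted mean of $-d$ over P2 leaves, and $N_1, N_2$ the participants
covered. This log-saturating form is the standard QUINT criterion
balancing the two components — within-leaf effect size and leaf
cardinality; the weights default to $a_1 = a_2 = 1$ and are configurable.
An assignment is admissible only with at least one P1 and one P2 leaf,
every P1 leaf at $d \ge d_{min}$ and every P2 leaf at $d \le -d_{min}$.
`optimal_assignment()` maximizes $C$ by exhaustive enumeration over the
$3^L$ assignments ($L \le 8$), breaking ties toward more P3 leaves and
then by lexicographic class order — both rules exist purely for
reproducibility.

Because $d_{min} > 0$ makes P1- and P2-eligibility mutually exclusive, the
maximization decomposes into two independent best-subset problems; the
split-search fast path exploits this, and a property test asserts its exact
agreement with the exhaustive enumeration.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `a1`, `a2` | 1, 1 | weights of effect-size and cardinality components |
| `dmin` | 0.30 | minimum \|d\| for a P1/P2 leaf; 0.30 is a conventional small-to-moderate effect floor, below which calling a leaf "responder" would not be clinically meaningful |
| `max_leaves` | 8 | maximum leaves grown |
| `min_per_arm` | 10 | minimum participants per arm per leaf; 10 matches the smallest per-arm leaf size printed in the published per-leaf tables |
| `boot` | 200 | bootstrap samples for pruning |
| `c_se` | 1 | SE-rule multiplier for size selection |

## Growth, the root reference, and pruning

Growth is greedy. Candidate thresholds are midpoints of consecutive
distinct observed values of each predictor within each leaf (ordinal and
binary predictors are treated as numeric; a value equal to the threshold
routes left). A split is inadmissible if any child arm falls below
`min_per_arm`. At every step the split maximizing the criterion (under the
optimal assignment of the *whole* resulting leaf set) is applied;
criterion ties are broken by earlier leaf, earlier predictor, smaller
threshold. Growth stops when no split improves the criterion or
`max_leaves` is reached.

The degenerate all-P3 root has no admissible assignment, so its criterion
needs a reference value. We assign it

$$C_{root} = 2a_1\log(1+d_{min}) + 2a_2\log(1/2),$$

the score of a minimally eligible, perfectly balanced qualitative
partition. The interpretation: a split is only worth making if it scores at
least as well as the *weakest* partition one would be willing to call a
qualitative interaction. This choice — the pruning rule is genuinely open,
as the underlying methodology only states that sizes should
"significantly improve" the criterion — gives the engine both of its
required operating characteristics at once: on null data spurious splits
(small, noise-driven subgroups with heavy cardinality penalties) score
below $C_{root}$ and the fit stays at the root, while genuinely planted
balanced interactions score above it and are kept.

Pruning (`prune = TRUE`, the default) follows the bias-corrected bootstrap:
for each size $k$ in the nested growth sequence, $B$ stratified-by-arm
resamples are drawn, a tree is regrown to size $k$ on each, and the
optimism $o_k$ is the mean of (criterion on the resample) − (the same
fitted tree and class assignment evaluated on the original table), with
$SE_k$ the SD of those differences. The selected size is the smallest $k$
with $\hat C_k = C_k - o_k \ge \max_j \hat C_j - c_{se}\,SE_{j^*}$. The
root enters this comparison with $\hat C_1 = C_{root}$, $o_1 = SE_1 = 0$.
Leaf classes are re-derived on the full table after pruning. Bootstrap
refits keep their own class assignment when evaluated on the original
table (the standard "frozen model" optimism logic); out of sample
$1 + D$ can in principle be non-positive, so it is floored at 0.01 inside
the transported evaluation only — in-sample evaluations use arithmetic
bit-identical to the search, which is why a degenerate identity-resample
bootstrap yields optimism exactly 0.

Resampling is stratified by arm to preserve the 1:1 design. Bootstrap
refits that admit no qualitative interaction are dropped from the averages
and counted.

## Validation and model comparison

`optimism_range()` estimates the optimism of the *effect-size range* — the
spread between the largest and smallest leaf effect, the quantity a QUINT
analysis is most prone to overstate. For each of $B$ resamples a tree with
the primary fit's leaf count is regrown; `range_boot` (its leaf-effect
spread on the resample) is compared with `range_orig` (the same tree's
leaves evaluated on the original table), and $\bar O_{range}$ is the mean
difference. Positive values mean overestimation. The default scale is
Cohen's $d$, with the mean-difference (`delta`) scale available: published
validation arithmetic for a percent-change model (optimism 0.64 against an
observed range 1.12, ~57% inflation) is consistent with the delta scale,
while the companion raw-change numbers are not reconcilable with either
scale from the published per-leaf rows alone — both scales are therefore
exposed and the report records which one was used. Bootstrap refits are
grown to *at most* the requested leaf count; replicates reaching fewer than
2 leaves are dropped and counted.

`cross_outcome_table()` routes the participants through each fitted tree
and computes Cohen's $d$ with 95% CI for every (tree, leaf, outcome)
combination, which shows whether trees trained on different outcome
definitions predict similar treatment effects. Leaves with an arm emptied
by an outcome's complete-case subset keep their row with `d` omitted.

## The synthetic trial generator

No participant-level data ship with the package; every test and the
acceptance script run on synthetic trials with known ground truth
(`generate_trial()`). The generator emulates the *structure* of a
multisite alcohol pharmacotherapy trial, not any real trial's numbers:

* **Design**: `n = 338` participants by default across 10 sites, 1:1
  permuted-block randomization (block size 4) stratified by site, so
  per-site arm imbalance never exceeds half a block.
* **Covariates**: a Gaussian copula with mixed marginals — log-normal
  drinking quantities, 1–10 motivation/confidence ratings, bounded integer
  symptom scores, binary sex/smoking, and six consequence items forming one
  scale, two of which receive high "Not Applicable" rates (25% and 10%) to
  exercise the item-exclusion rule. Correlations: drinking block 0.55,
  mood block 0.50, motivation–confidence 0.35, items 0.45.
* **Planted truth**: subgroups are threshold conjunctions over covariates
  that must partition the covariate space (checked at generation); each
  carries a true standardized effect $d$, positive favoring active. The
  default plants a qualitative interaction of $\mp 0.45$ around the
  motivation midpoint — moderate effects consistent with an
  overall-null trial.
* **Outcome model**: a proportion-change latent
  $pc = \mu + d\,\sigma\,(\mathbb 1[\text{active}] - 1/2) + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, with $\mu = 0.25$, $\sigma = 0.30$,
  clipped to the feasible range of a proportion of heavy days and realized
  as daily records: baseline days −28..−1 carry exactly the baseline heavy
  count, maintenance days 8..175 carry
  `round(phdd_base·(1−pc)·168)` heavy days, heavy days get drinks at or
  above the sex threshold. The symmetric arm shift and a baseline %HDD
  marginal bounded at 24/28 keep clipping mass below about 1% per side, so
  the realized per-subgroup standardized difference matches the configured
  $d$ (asymptotic bias ≤ 0.006 at the default effect sizes; tested at
  n = 10,000 within ±0.05, seed-averaged because the per-seed Monte Carlo
  error is itself ≈ 0.028). A `tlfb = "none"` fast path computes the
  identical outcome values without materializing daily records (the
  equality is tested) and is used in bootstrap-heavy simulations.
* **Missingness**: 17.75% of participants lose the whole maintenance phase
  (optionally MAR via a logistic dependence on baseline drinks/week, which
  lets the exclude-vs-impute comparison diverge); item-level
  "Refuse to Respond" rates of 2–3%; 5% of maintenance days unobserved for
  retained participants; 6% of weekly compliance entries missing.

What the generator does **not** emulate: real covariate distributions or
their tails, serial dependence of drinking across days (days are
exchangeable within a phase given the heavy count), site effects on
outcomes, titration-week drinking, and informative *item*-level
missingness. Passing tests therefore demonstrate algorithmic correctness
and recovery under the stated conditions, not performance guarantees on
real trial data.

## Numerical and testing choices

* Split scans compute child arm statistics from prefix sums; variances are
  floored at 0 against cancellation, and pooled-SD-zero children are
  scored as $d = 0$ (they cannot be eligible).
* Trees serialize to JSON with doubles at 17 significant digits, so
  write → read → write is byte-identical and a reloaded tree routes
  records exactly as the original.
* Determinism: a single integer seed governs generation, imputation and
  every bootstrap; identical seeds give byte-identical tables, trees and
  reports end to end.
* The optimized engine (incremental scans plus the eligibility
  decomposition) is verified against a naive reference implementation of
  the same sequential search — every candidate scored directly with
  `leaf_effect()` and `optimal_assignment()` — over a hundred small
  instances (n = 24, two predictors, up to three leaves), and the greedy
  first split is additionally checked against the global two-leaf optimum,
  where greedy search is provably global. Greedy growth is *not* globally
  optimal over all trees: the best three-leaf tree can pass through an
  inadmissible or non-maximal two-leaf state, a path a sequential
  qualitative-interaction search cannot take by construction. This is a
  property of the method, not of the implementation.
* Simulation sizes used by the test suite and acceptance script were
  chosen as the smallest that give stable operating characteristics:
  recovery and null-specificity runs use n = 600 with 50 bootstrap
  samples for pruning across 50 seeds; null-optimism runs use n = 160
  with B = 200; the convergence check uses n = 10,000 averaged over three
  seeds.

## Known limitations

* Only two arms, numeric-only splits, no surrogate splits for missing
  predictor values (predictors must be imputed first), no honest
  (sample-splitting) inference on leaf effects — the per-leaf CIs are
  descriptive and inherit the selection optimism the validation module
  quantifies.
* The criterion weights, `dmin`, minimum leaf size and the root reference
  value are analysis choices; sensitivity to them should be reported in
  applications.
* With eight leaves the exhaustive assignment enumeration is 6561
  evaluations per candidate set — fast here, but the design would not
  extend far beyond `max_leaves = 12` without replacing the enumeration.
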