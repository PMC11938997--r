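# quintree

Qualitative interaction trees (QUINT) for two-arm randomized trials, with a
complete preparation pipeline for daily-drinking (timeline-followback)
outcomes and a synthetic trial generator for method evaluation.

## The problem

A randomized trial can be null on average while still helping some
participants and harming others. Qualitative interaction trees search the
baseline covariate space for exactly this situation: they recursively
partition participants into leaves with *homogeneous treatment effects* and
label every leaf as

* **P1 — treatment responder**: the active arm beats placebo,
* **P2 — iatrogenic responder**: placebo beats the active arm,
* **P3 — nonresponder**: no appreciable difference.

`quintree` implements the full analysis pipeline used in secondary analyses
of alcohol pharmacotherapy trials: deriving heavy-drinking-day endpoints
from daily drinking records, handling item- and outcome-level missingness,
fitting and pruning the tree, validating the effect-size spread with a
bootstrap optimism estimate, and comparing models trained on different
outcomes.

## The model

Within a leaf, the treatment effect is Cohen's
*d* = (x̄_active − x̄_placebo) / s_pool, with s_pool² the
degrees-of-freedom-weighted pooled variance; positive *d* means the active
arm reduces drinking more. A class assignment of the leaves is scored by

C = a₁·[log(1 + D₁) + log(1 + D₂)] + a₂·[log(N₁/N) + log(N₂/N)]

where D₁ is the size-weighted mean *d* over P1 leaves, D₂ the size-weighted
mean of −*d* over P2 leaves, and N₁, N₂ the participants they cover. The
criterion rewards both large opposite-signed effects and large subgroups. An
assignment is admissible only if at least one P1 and one P2 leaf exist, with
every P1 leaf at `d ≥ dmin` and every P2 leaf at `d ≤ −dmin` (default
`dmin = 0.30`).

Growth is greedy over all (leaf, predictor, threshold) candidates with the
optimal assignment recomputed exhaustively for every candidate; tree size is
then selected by a bias-corrected bootstrap: the apparent criterion of each
nested size is penalized by the mean optimism of refits on resamples, and
the smallest size within one SE of the best corrected criterion wins. The
same bootstrap logic powers the validation statistic O_range — the average
amount by which the spread between the largest and smallest leaf effect is
overestimated by fitting and evaluating on the same data.

Heavy drinking days follow the standard sex-specific thresholds (≥4 standard
drinks for females, ≥5 for males). Outcomes are the proportion change
(base − maintenance)/base in %HDD, and the raw change scaled to days per
28-day period.

## Worked example

```r
library(quintree)

# a synthetic 338-participant trial with a planted qualitative interaction
trial <- generate_trial(sim_config(n = 338, seed = 1))

# preparation: compliance zero-fill, item exclusion, chained imputation,
# scale scoring, TLFB-derived outcomes, dropouts excluded
prep <- prep_trial(trial$table, default_schema(), tlfb = trial$tlfb,
                   missing_outcomes = "exclude", seed = 1)

fit <- quint(prep, "prop_change",
             c("motivation", "confidence", "anxiety", "drinks_per_week",
               "drinks_per_day", "impulsivity"),
             control = quint_control(boot = 200), seed = 2)
fit
#> <quint_tree> outcome: prop_change  n = 275  leaves = 2
#>   criterion: -0.3715
#>   leaf 1 [P2] n=65+68 d=-0.79  motivation ≤ 6.5
#>   leaf 2 [P1] n=70+72 d=+0.54  motivation > 6.5
```

The fit recovers the planted structure: participants with motivation ≤ 6.5
respond better to placebo (iatrogenic, d = −0.79), those above respond
better to the active arm (d = +0.54). `tidy(fit)` returns the per-leaf
table (arm sizes, means, SDs, ΔMean, SE, *d*, 95% CI), `glance(fit)` the
one-row fit summary, `autoplot(fit)` the leaf-effect plot, and
`write_quint_tree(fit, "tree.json")` a full-precision serialization.

Validation of the fitted spread:

```r
rep <- optimism_range(prep, "prop_change",
                      c("motivation", "confidence", "anxiety"),
                      leaf_count = 2, B = 1000, seed = 3)
rep
#> <optimism_report> outcome: prop_change  leaves: 2  B = 1000
#>   O_range = 0.0516 on the d scale (927 replicates, 73 dropped)
#>   observed range = 1.3332; estimated inflation = 3.9%
```

`O_range > 0` quantifies how much the apparent leaf-effect spread
overstates what would replicate; with a strongly planted interaction the
bias is small — the spread of 1.33 on the *d* scale is estimated to be
inflated by only about 4% (replicates whose refit admits no qualitative
interaction are dropped and counted).

A thin command-line wrapper over the same functions ships in
`inst/cli/quintree.R` with `simulate`, `prep`, `fit`, `validate` and
`compare` subcommands.

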