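# glycomatch

Within-subject matched-pairs estimation of the acute glucose-lowering effect
of short physical-activity (PA) bouts in type 1 diabetes, from free-living
CGM, insulin and activity logs.

## The problem

Above-target glucose (>10 mmol/L) is usually corrected with insulin, which
acts slowly and variably. Short (10–30 min) activity bouts lower glucose
through insulin-independent mechanisms, but free-living before/after
comparisons confound the activity effect with what glucose would have done
anyway — mean reversion from a high starting point and residual insulin
action. `glycomatch` emulates the ideal within-subject experiment: every
eligible PA bout (duration 10–30 min, starting glucose >10 mmol/L) is paired
with a non-PA control window of equal duration from the *same* participant,
matched on the physiological state at onset, and the paired contrast of the
glucose change from onset to 20 min post-event estimates the
PA-attributable effect.

## The method

For each event window the package computes four onset covariates: starting
glucose (nearest CGM reading), glucose rate of change (mean of the three
prior 5-min slopes, `(G(t0) − G(t0−15))/15`), the prior-hour glucose CV, and
insulin on board (linear 4-h decay of bolus insulin per kg). Control windows
are enumerated on the CGM grid outside overnight hours (23:00–06:00) and
outside 1 h before to 4 h after any PA bout, with a 40-min anti-overlap
guard. Matching is weighted k-nearest-neighbour within participant:
outcome-derived weights (absolute standardized coefficients of a mixed model
of glucose change on the z-scored covariates), per-variable calipers of
0.2 × pooled SD, selection without replacement, best-first order. Balance is
reported as standardized mean differences (acceptable below 0.1).

The effect model is a three-level linear mixed model — windows nested in
matched pairs nested in participants —

```
Δglucose ~ condition × (starting glucose, ROC, CV, IOB, duration,
                        clock time, age, BMI, HbA1c; all centred)
           + (1 | participant) + (1 | pair)
```

whose `condition` coefficient is the average differential effect and whose
interactions are physiological moderators (reported per 0.1 mmol/L/min of
faster decline, per 1 mmol/L lower starting glucose, and so on). A logistic
mixed model (with a Firth-penalized fallback for the usual sparse-event,
near-separated case) quantifies hypoglycaemia risk (<3.9 mmol/L during the
window or within 20 min after), and a sensitivity analysis re-estimates the
effect after excluding bouts with intra-window insulin or carbohydrate. A
starting-glucose × rate-of-change heatmap turns the fitted model into a
decision tool.

Because the real cohorts behind this design are available only on request,
the package ships a calibrated synthetic-cohort generator
(`generate_cohort()`) with a known causal structure — mean-reverting glucose
dynamics, meal and bolus excursions, sensor noise, daytime activity bouts
carrying a moderated effect of −1.9 mmol/L at the eligible covariate means —
so every stage of the pipeline is testable against ground truth. See the
methods vignette (`vignettes/glycomatch-methods.Rmd`) for the full model and
every calibration choice.

## Worked example

```r
library(glycomatch)

cfg    <- sim_config(n_participants = 60)   # defaults: 28 days, 5-min CGM
cohort <- generate_cohort(cfg, seed = 7)
res    <- analyze_cohort(cohort)

res$counts
#> candidate_bouts        eligible         matched        analysed
#>             809             195             115             115

res$balance
#> <balance_report> 115 matched, 80 dropped
#>       variable     before         after
#>  start_glucose  1.5115370  0.0133969836
#>            roc  0.1394117  0.0131837985
#>         cv_pre -0.3900953  0.0240111491
#>            iob  0.2142606 -0.0009965332

res$primary_model
#> <glyco_effect_model>
#>   230 observations, 115 pairs, 46 participants
#>   PA vs control: -1.64 mmol/L [95% CI -2.11, -1.18], p 5.6e-12
#>   moderators (per reporting unit):
#>     roc_decline  -0.801 [-1.718, 0.116]
#>     start_lower  -0.341 [-0.807, 0.125]
#>     ...
```

Reading this: of 809 simulated bouts, 195 start above 10 mmol/L with
computable covariates; 115 find a same-participant control inside all four
calipers, after which every covariate is balanced (|SMD| ≤ 0.024, versus up
to 1.51 before matching). The mixed model attributes a −1.64 mmol/L
[−2.11, −1.18] glucose change to activity at this small cohort size
(the generator's true average effect is −1.9), steeper when glucose is
falling faster at onset (`roc_decline`, per 0.1 mmol/L/min). At 500
participants the estimate tightens onto the truth — that experiment is what
`scripts/acceptance.R` runs.

The same pipeline runs from CSV files (`cgm.csv`, `doses.csv`, `bouts.csv`,
`participants.csv`, optional `carbs.csv`) via
`run_pipeline(data_dir = ..., out_dir = ...)`, which writes every
intermediate artifact (windows, pairs, balance, model JSONs, heatmap,
cohort table) plus a reproducibility manifest; a thin command-line wrapper
lives at `inst/scripts/glycomatch.R`.

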