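---
title: "Methods: within-subject matched-pairs estimation of the acute glucose effect of short activity bouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-subject matched-pairs estimation of the acute glucose effect of short activity bouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomatch)
```

## The question and the design

People with type 1 diabetes frequently sit above the 10 mmol/L glycaemic
target and correct with insulin, whose onset is slow and variable. Short
(10–30 min) bouts of physical activity (PA) are a candidate
non-pharmacological adjunct: they lower glucose through insulin-independent
glucose uptake. Free-living CGM + insulin + activity data can quantify that
effect, but naive before/after comparisons confound the PA effect with what
glucose *would have done anyway* — above-target glucose drifts back toward an
individual's set-point, and recently dosed insulin keeps acting.

`glycomatch` implements a within-subject matched-pairs emulation of the ideal
experiment. Every eligible PA bout (10–30 min, starting glucose strictly
above 10 mmol/L) is paired with a non-PA control window of *equal duration
from the same participant*, selected to match the physiological state at
onset. The outcome is the change in sensor glucose from window onset to
20 min after the window ends (the tail absorbs CGM lag). The contrast of PA
versus matched control windows is then the acute, PA-attributable glucose
change, with within-subject pairing removing all stable person-level
confounding (age, sex, insulin modality, HbA1c, sensor behaviour).

## Event-anchored covariates

Four covariates summarize the physiological state at window onset and drive
both confounding and effect modification:

* **Starting glucose** — the CGM reading nearest the onset, within a snap
  tolerance of ±2.5 min (half the 5-min cadence; the data never guarantee a
  reading exactly at onset).
* **Rate of change (ROC)** — the mean of the three 5-min slopes immediately
  before onset; on a gap-free grid this telescopes to
  `(G(t0) − G(t0−15)) / 15` mmol/L/min.
* **Prior-hour CV** — 100 × SD/mean over readings in `[t0 − 60, t0]`,
  computed when at least 75% of the 12 readings expected in an hour are
  present. The onset reading is included; with balance assessed by SMD after
  matching, the boundary choice is immaterial.
* **Insulin on board (IOB)** — the sum of residual bolus insulin under a
  linear 4-h decay, divided by body weight (U/kg). Only rapid-acting boluses
  count; basal delivery is excluded, as IOB conventionally tracks bolus
  insulin. The linear 240-min action curve is a deliberate simplification:
  it is transparent, monotone, and adequate for a matching covariate.

Any window for which a covariate is not computable is excluded rather than
imputed — a missing-covariate signal, never a guess.

## Eligibility and control-window enumeration

A participant contributes only with ≥70% CGM availability over the wear
period. Control candidates are enumerated at a 5-min stride (the CGM grid —
the finest resolution at which covariates change) and must:

1. not intersect the overnight period, 23:00–06:00 (the data never define
   "overnight"; this bracket covers typical sleep and is configurable) —
   sleep physiology and unobserved nocturnal corrections make overnight
   windows poor counterfactuals for daytime activity;
2. not intersect `[onset − 1 h, end + 4 h]` of **any** of the participant's
   PA bouts — acute and residual exercise effects contaminate those periods;
3. stay ≥40 min clear of the matched bout's own window (implied by rule 2
   but enforced independently), and, once selected, a control blocks a 40-min
   guard band against later selections so matched periods never overlap;
4. have all four covariates computable and a readable endpoint at
   `end + 20 min`.

Control windows are *not* required to start above 10 mmol/L: the caliper on
starting glucose enforces closeness instead, so the control arm is matched
rather than filtered. Control windows may fall before or after their bout,
at any admissible time of day.

## Matching: weights, calipers, greedy kNN

Matching variables are the four onset covariates. Duration needs no caliper
— candidates are constructed with exactly the bout's duration — and clock
time is deliberately *not* a matching variable: controls may come from
anywhere in the record, and time of day is adjusted for in the outcome model
instead. (Screening diagnostics for clock time and duration are still
reported, and `extra_vars` can promote them into the matching set.) This
choice matters at scale: with thousands of bouts even a physiologically
trivial clock-time correlation becomes "significant", and a caliper of
0.2 SD on clock time (≈ ±50 min) would gut the candidate pools while adding
no confounding control that the model does not already provide.

Weights come from the data: candidate variables are screened by univariate
Pearson correlation with the PA-window glucose change; the z-scored matching
variables then enter a linear mixed model of the outcome with a participant
random intercept, and each variable's weight is its absolute standardized
coefficient, normalized to sum to one. If no core variable survives the
univariate screen — as with a pure-noise outcome — the weights fall back to
equal across the four (the model's coefficients would be noise, and equal
weighting is the honest prior).

Calipers are 0.2 × the pooled SD of each variable. The pooled set is all
eligible PA windows plus all control candidates: the matched distribution
does not exist before matching, and this pre-match pool is its natural
stand-in (an optional second pass after a provisional match is supported but
off by default, as it changes balance only marginally).

Each bout is then paired to the minimum-weighted-distance admissible
candidate (weighted Euclidean distance on z-scores; every per-variable gap
must sit inside its caliper). Selection is without replacement within
participant, so no control data are reused — reuse would quietly inflate
precision. Bouts are processed best-first (globally smallest current best
distance first), which makes the result invariant to input order; distance
ties resolve to the earlier-onset candidate. Bouts with no admissible
candidate are dropped and reported. Match quality is summarized by
standardized mean differences before and after matching; |SMD| < 0.1 is the
acceptability threshold.

**What caliper matching estimates.** Bouts with extreme covariate
combinations (very high CV, extreme ROC) are the ones that fail to find
admissible controls, so the matched sample is mildly tilted toward typical
physiology. The condition effect reported by the model is the average
differential effect *in the matched sample* — exactly the estimand a
matched-pairs study reports — and on the synthetic cohort it tracks the
matched bouts' ground truth to within ~0.01 mmol/L, while sitting
0.05–0.15 mmol/L above the eligible-population mean effect. This is a
property of the design, not an estimation error, and it is why the matched
rate (≈60% here, with four joint calipers over a 28-day record) is reported
alongside every fit.

## The outcome models

The primary model is a three-level linear mixed model: observations (one
glucose change per window) nest in matched pairs, which nest in
participants:

```
delta_glucose ~ pa * (start_glucose + roc + cv_pre + iob + duration +
                      clock_time + age + bmi + hba1c)   [all centred]
                + (1 | participant) + (1 | pair)
```

Continuous covariates are centred at their sample means, so the `pa`
coefficient is the average differential effect of PA over matched non-PA
periods, and each `pa:` interaction is a moderator of that differential.
Quadratic terms of the event-level covariates are tested by single-term Wald
tests at α = 0.05 (cubics only where a quadratic is retained) and kept only
when significant. Inference is Wald throughout — estimates ± 1.96 SE and
normal p-values; at these sample sizes profile or bootstrap intervals differ
negligibly and Wald keeps the fitting engine swappable. If the full random
structure fails, the model refits without the pair intercept and flags
itself.

**Moderator reporting conventions.** Moderators are reported per unit in the
direction conventionally associated with a larger glucose reduction, which
is how this literature states them: ROC per 0.1 mmol/L/min of *faster
decline*, starting glucose per 1 mmol/L *lower*, BMI per 1 kg/m² *lower*,
and CV (per 1%), duration (per minute), IOB (per 0.1 U/kg) and age (per
year) per unit increase. The synthetic generator's `effect_slopes` use the
same scales, so recovery is read off directly.

Hypoglycaemia (any reading strictly below 3.9 mmol/L during the window or
within 20 min after; a coverage gap above 10 min makes the window
indeterminate) is modelled by logistic mixed regression on condition,
starting glucose, duration, age, BMI, ROC and modality with a participant
intercept. Hypoglycaemia after short PA from above 10 mmol/L is rare, so the
events are usually sparse and concentrated in the PA arm; when either arm
has fewer than five events the mixed fit is replaced by Firth-penalized
logistic regression (Jeffreys-prior penalization, the standard
finite-estimate remedy for separation), and the result is flagged. Zero
events return a structured "no events" result. A cohort-scale odds ratio
against a near-zero baseline rate is numerically huge and unstable by
nature; the incidence proportions are the quantity to read.

The sensitivity analysis re-runs the primary model after excluding pairs
whose *PA window* contains any bolus or carbohydrate record between onset
and 20 min post-event. The covariate set is unchanged: intra-window intake
is a post-exposure event (often a reaction to the glucose drop itself), so
adjusting for it — rather than excluding — would condition on a mediator.

## The decision-tool heatmap

`predict_grid()` evaluates the fitted fixed effects over starting glucose
(default 10–16 mmol/L by 0.5 — the observed starting-glucose IQR plus
margin) × ROC (−0.15 to +0.15 mmol/L/min by 0.025) for both conditions, at a
reference bout of 23 min (the median duration) with all other covariates at
their sample means. Cells outside the central 95% of the observed
starting-glucose or ROC distribution are flagged extrapolated.

Inside the supported region the PA surface sits below the control surface at
every cell. On the full default grid that dominance is *not* guaranteed: the
fitted moderator structure (a smaller differential at higher starting
glucose and rising ROC) is linear, so at the extreme corner — glucose
16 mmol/L with ROC +0.15 mmol/L/min, several SDs outside the observed
covariate support — the extrapolated linear surfaces can cross. This is a
statement about extrapolation, not physiology; such cells are flagged and
should not be read as advice. The mg/dL rendering multiplies all glucose
quantities by 18.016 (molar mass of glucose; exactly linear and invertible).
Plots anchor the colour scale at zero change, warmer colours meaning larger
predicted reductions.

## The synthetic cohort generator

The generator exists so every stage has a known ground truth; its defaults
are the study conditions the package validates against.

* **Shared dynamics.** Glucose is a discrete-time mean-reverting
  (Ornstein–Uhlenbeck-style) walk on the 5-min grid around an individual
  set-point (`mu_glucose` ≈ N(8.4, 1.2) mmol/L), with per-step reversion
  `ou_reversion = 0.023` and innovation SD `ou_sigma = 0.50` mmol/L.
  Mean reversion is the generator's stand-in for everything that pulls
  elevated glucose down absent activity (basal insulin, renal clearance);
  the reversion default is calibrated so an average *matched control
  window* changes by `drift_nonpa = −0.3` mmol/L over its measurement span
  — the behaviour the pipeline's control arm must exhibit. A first-
  principles value derived from the reversion alone undershoots, because
  meal-peak highs do not revert; the default was therefore set by
  simulation.
* **Meals and boluses.** Poisson meals (3/day, daytime) add
  rise-then-decay excursions (peak ~Gamma, mean 3 mmol/L; total span
  60–120 min); 90% of meals carry a bolus (Gamma, mean 4 U) whose effect
  follows the same linear 4-h action curve used for IOB, scaled by
  `insulin_action = 0.25` mmol/L/U; occasional standalone corrections
  (0.5/day) vary IOB independently of meals. Basal delivery appears in the
  dose log (one record per day) so the IOB computation's basal-exclusion
  rule is exercised.
* **Sensor noise** is i.i.d. N(0, 0.25) mmol/L, and traces clip to the
  sensor range 2.2–22.2 mmol/L.
* **PA bouts** (10–16 per participant over 28 days — a 4-week wear like the
  free-living studies this emulates) are placed in daytime (06:00–23:00),
  non-overlapping, separated by >5 h so each bout owns clean exclusion
  zones. Durations are `10 + 20·Beta(2.4, 1.4)` min, giving a median of
  23 min. Roughly 30% of bouts start above 10 mmol/L, yielding ≈1800
  eligible bouts from 500 participants.
* **The causal effect.** Each bout receives
  `Δ_b = −1.9 + s·(u_b − ū) + b_i + ε_b` mmol/L, applied as a uniform ramp
  over the bout plus its 20-min tail (only the endpoint change is measured,
  so the intra-window shape is free) and decaying back over the following
  3 h. The slopes `s` are the calibrated moderator values
  (−0.90 per 0.1 mmol/L/min faster decline, −0.16 per mmol/L lower start,
  −0.06 per % CV, −0.05 per minute, −0.56 per 0.1 U/kg IOB, −0.01 per year,
  −0.05 per kg/m² lower BMI); `u_b` are the bout's onset covariates
  *computed with the pipeline's own feature functions on the noisy trace*,
  so fitted interactions are compared against exactly what was injected.
  Covariates are centred at their means over eligible bouts, making the
  intercept the mean differential effect in the analysed population.
  `b_i ~ N(0, 0.3)` is a participant random effect; `ε_b ~ N(0, 1.8)` is
  bout-level noise, set so that 1–2% of PA bouts dip below 3.9 mmol/L —
  hypoglycaemia is emergent (a trace crossing the threshold), never
  injected. The realized `Δ_b` of every bout is recorded in `truth`.
* **Rescue carbohydrates.** When glucose falls below 5 mmol/L inside a PA
  measurement window, a 15 g rescue intake follows with probability 0.7,
  raising glucose with a lagged meal-type kernel and appearing in the
  carbohydrate log. This reproduces the treatment-reaction structure that
  motivates the sensitivity analysis: treated bouts are the large-drop
  bouts, so excluding them attenuates the estimate.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: CGM dropouts and compression artifacts (traces
are gap-free; the availability and gap rules are tested on constructed
traces instead), right-skewed glucose distributions (the symmetric walk
matches the mean and CV anchors but overstates time below range relative to
a real cohort), accelerometer-derived bout detection, meal announcement
errors, circadian insulin-sensitivity rhythms, and any delayed (multi-hour)
exercise effects. Conclusions about those features need real data.

## Numerical and degenerate-input choices

* Reading snap tolerance ±2.5 min everywhere (half the nominal cadence);
  equidistant readings resolve to the earlier one.
* The rolling-CV track subtracts the trace mean before forming cumulative
  sums and clamps variances below 1e−10 to zero, so constant (sensor-
  clipped) windows give exactly 0% CV, matching the direct computation.
* SMD with zero pooled variance is 0 when the means agree, `Inf` otherwise.
* Matching distance ties break by candidate onset, then bout onset;
  candidate enumeration uses open-interval overlap, so windows may touch an
  exclusion boundary exactly.
* Zero hypoglycaemia events, complete separation, tiny filtered samples and
  empty candidate sets all return structured results rather than errors.
* Problem sizes used by the validation suite: five replicates of the
  default 500-participant cohort for the headline quantities; 100
  replicates at 100 participants × 21 days for moderator CI coverage; 100
  replicates at 60 participants × 14 days for null calibration; 1000
  randomized small instances for the matching oracle. These sizes give
  Monte-Carlo error comfortably inside the assertion tolerances while
  keeping a full run on one CPU inside a coffee break.

## Known limitations

* The IOB model ignores insulin stacking nonlinearity and individual action
  times; it is a matching covariate, not a dosing tool.
* With four joint calipers, roughly 40% of eligible bouts go unmatched on a
  28-day record; the estimand is the matched population (see above).
* The hypoglycaemia odds ratio under near-separation is reported with a
  penalized fit and wide intervals; treat the incidence proportions as the
  primary safety readout.
* The heatmap is a description of the fitted model, not clinical advice;
  extrapolated cells are flagged and excluded from the dominance guarantee.
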