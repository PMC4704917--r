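---
title: "Validating reported energy intake against armband energy expenditure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating reported energy intake against armband energy expenditure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietsense)
```

## The problem

Self-reported food records systematically understate what adolescents eat.
The standard way to quantify that bias without doubly labelled water is to
compare reported energy intake (EI, kJ/day) with an objective estimate of
total energy expenditure (TEE): in weight-stable people EI should match
TEE, so the ratio EI/TEE measures reporting accuracy, and a participant is
called a *plausible* reporter when EI falls within ±5 % of TEE, an
*under-reporter* below, an *over-reporter* above.

`dietsense` implements the computational machinery of a mobile food-record
assessment for 14–16-year-olds and its evaluation against a wearable
armband (SenseWear-style) reference:

* **intake**: per-meal item records, a portion-aware food-composition
  database (per-100 g energy in kJ plus an open set of nutrient columns),
  and daily energy/nutrient aggregation;
* **expenditure**: basal metabolic rate (BMR) from Schofield's
  weight-based equations, app-style TEE as BMR × a five-level
  physical-activity multiplier (PAL), and reference TEE from minute-level
  armband traces;
* **evaluation**: day-level inclusion filters, per-participant accuracy
  metrics and misreporting classification, Bland–Altman agreement,
  Spearman correlations, group comparisons, and stepwise regression of
  reporting accuracy on participant factors;
* **simulation**: a seeded generator of complete synthetic cohorts, so the
  whole pipeline is testable end to end without any restricted data.

## Energy models

**BMR.** Schofield's weight-only equations predict BMR as
`a × weight + b` with sex- and age-band-specific coefficients
(`schofield_coefficients()`, stored in kJ/day). Age bands are
lower-inclusive, so an exact band boundary (18.0 y) falls in the older
band. For a 15.5-year-old girl weighing 57.4 kg:

```{r}
schofield_bmr("female", 15.5, 57.4)
```

**PAL.** The daily activity question has five ordered levels, *very
light* to *very heavy*, mapped to sex-specific multipliers — girls
1.3/1.5/1.7/1.9/2.1, boys 0.1 higher at every level — and
`tee_app() = schofield_bmr() × pal_value()`.

```{r}
pal_table()
```

**Armband TEE.** A wear day is 1440 minute slots of energy expenditure
with an on-body flag. Off-body minutes are imputed at basal rate
(`bmr/1440` per minute), mirroring the device's own behaviour, so
`tee_swa()` is never less than the on-body sum. Wear time below 19 h
(80 % of the day) excludes the day; reported intake below 2092 kJ
(500 kcal, at the fixed 4.184 kJ/kcal conversion used throughout)
excludes the day. Both thresholds are arguments, with those defaults.

**Classification.** `classify_reporting()` uses a ±5 % plausibility band
with *inclusive* boundaries; the half-width is an argument. Agreement is
summarised by `bland_altman()` with limits of agreement
`mean ± 1.96 × SD` (sample SD, n−1); both the multiplier and the minimum
pair count (3 by default, lowerable to 2 where the sample SD is still
defined) are arguments.

## Questionnaire scoring

The 53-item questionnaire bundles five borrowed instruments
(conscientiousness, fear of negative evaluation, social desirability, and
the three TFEQ-R18 eating-behaviour subscales — 9 uncontrolled-eating, 6
cognitive-restraint, 3 emotional-eating items), body-size figure ratings,
two frequency questions and four attitude questions. Item ids, scale
ranges, reverse keys and the subscale partition live in a declared JSON
config (`instrument_config()`), not in code: the original instruments'
exact keys belong to their source publications, so the config states the
keys this package scores with and accepts alternatives.

Indices use the linear min–max transform
`100 × Σ(item − min) / (n × (max − min))` after flipping reverse-keyed
items, giving a 0–100 range with all-minimum → 0 and all-maximum → 100.
Whether the original analyses used exactly this transform is not
derivable from the published range alone; the transform is declared here,
and the config permits instrument-specific alternatives.

Imputation (`impute_missing()`) follows fixed rules: missing figure
ratings become *no discrepancy*; missing breakfast frequency becomes 7
days/week and school lunch 5 days/week; missing conscientiousness items
take the neutral scale midpoint; missing social-desirability,
uncontrolled-eating and cognitive-restraint items take the per-item
median of the other respondents. Two extensions keep scoring total for
any missingness pattern: the median rule also covers the remaining
ordinal instruments, and missing attitude answers take the modal answer.
Every imputed cell is logged, and imputing complete data is the identity.

## The synthetic cohort

`generate_study()` draws, under a single seed:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 81 (50 girls / 31 boys) | cohort size |
| age | ~N(15.5, 0.35) y, clipped to 14–16 | recruitment window |
| height | girls ~N(165, 10), boys ~N(176.5, 8.9) cm | anthropometry |
| BMI z | ~N(0.44, 0.62) | drives weight via the LMS reference |
| `n_day_probs` | mode 3 (1–6) days | recording days per participant |
| `prop_weekend_days` | 0.40 | weekend days oversampled by start-day weighting |
| `true_pal_mean/sd` | 1.48 / 0.12 | true activity level (TEE/BMR) |
| `tee_day_cv` | 7 % | day-to-day TEE variation |
| `swa_noise_cv` | 10 % | armband day-level measurement noise |
| `wear_gap` | 60 ± 45 min, 5 % long gaps | off-body model |
| `underreport_ratio` | 0.71 | group-level median EI/TEE target |
| `ratio_between_sd` | 0.35 (log) | between-person reporting spread |
| `ei_day_cv` | 25 % | within-person day-to-day intake variation |
| `pal_overstatement` | 1.19 | target cohort TEE_app/TEE_SWA |
| `missing_rate` | 0.004/cell | ≈ one fifth of respondents with ≥ 1 gap |

Design choices that were genuinely open:

* **Reporting bias is multiplicative log-normal per participant** with
  median `underreport_ratio`, because EI/TEE is a ratio scale and both
  medians and means of ratios are reported downstream. Day-level intake
  noise is mean-one log-normal so a participant's day mean stays centred
  on their own ratio. The within-person day CV (25 %) is a declared free
  parameter: no published within-person variance was available to anchor
  it.
* **Accuracy effects default to off** (`weekend_bias = 0`,
  `bmi_z_bias_slope = 0`). Non-zero effects would displace the cohort
  median away from `underreport_ratio`; they exist to be *injected* in
  parameter-recovery experiments. When injected, both are applied
  centred — the BMI-z slope additively on the relative-accuracy scale
  around the cohort mean z, the weekend shift to all days of participants
  whose record contains a weekend day, centred on the share of such
  participants — so each injected value is exactly the estimand of the
  corresponding univariable regression while the cohort-level ratio
  target is untouched.
* **Reported activity answers are calibrated**: each day's answer is the
  level nearest to `true PAL × pal_overstatement × shrink`, where
  `shrink` is that day's expected armband-total reduction from basal-rate
  imputation of its off-body gap, plus a symmetric one-level jitter
  (15 %). This makes the cohort TEE_app/TEE_SWA ratio target
  `pal_overstatement` by construction, which is the generator's contract.
* **Meals are a greedy energy knapsack**: four meals with jittered energy
  shares, two to four foods each, gram amounts back-computed from the
  food's energy density (occasionally re-expressed in the food's portion
  unit). Recorded intake reproduces the day's target to well within 1 %;
  nutrient realism is explicitly not a goal.
* **The growth reference is synthetic.** Real LMS/cutoff tables are not
  redistributable, so the packaged reference
  (`bmi_reference_synthetic.csv`) has the LMS *structure* of standard
  references with cutoff curves anchored at adult BMI 17/18.5/25/30;
  `bmi_zscore()` and `weight_status()` accept any conforming table.

What the generator does **not** emulate: real food-selection behaviour,
correlated nutrient profiles, secular or seasonal intake patterns,
device-specific armband error structure (sensor drift, posture effects),
or informative missingness. Passing recovery tests therefore demonstrates
that the pipeline correctly measures what the generator encodes — not
that the instrument itself is valid in the field.

## Numerical conventions

* kcal↔kJ at exactly 4.184; 500 kcal = 2092 kJ after rounding.
* Per-participant aggregation is the mean over each metric's own included
  days; the intake and expenditure day sets need not match.
* Category and band boundaries are inclusive toward the more extreme
  category (weight status) or toward *plausible* (reporting class);
  day-filters are inclusive at their thresholds (≥ 2092 kJ, ≥ 19 h).
* Stepwise selection is forward entry at p < .05 with backward removal at
  p > .10 (F tests between nested models), the conventional defaults, and
  both thresholds are arguments. Reference TEE is excluded as a candidate
  for the relative outcome, which is already normalised by it. An exactly
  collinear candidate set raises a singularity error naming the columns.
* Ties in Spearman correlations use average ranks; fully tied paired
  comparisons report p = 1 by convention.
* A mixed-model check (`accuracy_regression_mixed()`) refits selected
  fixed effects with a school random intercept; its contract on
  well-conditioned data is only that the fixed effects are essentially
  unchanged.

## Problem sizes used by the test suite

Group-level recovery runs 20 seeded default studies of 81 participants
and compares the across-seed mean of the cohort medians with the
generator targets (±0.03). Effect recovery injects a +1500 kJ
weekend-record effect and a −0.12 relative-accuracy slope per BMI z unit
and checks univariable CI coverage over 60 replicate cohorts: at 20
replicates the binomial noise of a ~95 %-coverage interval would dominate
the ≥ 90 % criterion, at 60 it no longer does. These sizes were chosen so
the whole suite completes in a few minutes on a single core.

## A worked run

```{r, eval = FALSE}
study <- generate_study(sim_config(seed = 42))
res <- run_pipeline(study)
cohort_summary(res$evaluations)
table(res$evaluations$reporting_class)
ba <- bland_altman(res$evaluations$ei_kj, res$evaluations$tee_swa_kj,
                   res$evaluations$participant_id)
ba_plot(ba)

scores <- score_questionnaire(impute_missing(study$questionnaire)$responses)
dat <- regression_dataset(res$evaluations, scores)
accuracy_regression(dat, "rel_accuracy")
```

## Limitations

The package evaluates *reporting* accuracy against an armband-derived
reference that is itself an estimate; nothing here validates the armband.
The synthetic defaults encode one plausible adolescent cohort; any
conclusion about other populations requires re-anchoring the generator.
The questionnaire configs declare plausible scoring keys rather than
reproducing the licensed instruments.
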