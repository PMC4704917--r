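# dietsense

Validation tooling for mobile food-record dietary assessment in
adolescents: compute energy and nutrient intake from per-meal records,
estimate total energy expenditure (TEE) two ways — Schofield basal
metabolic rate (BMR) × a five-level physical-activity multiplier (PAL),
and minute-level armband traces with basal-rate imputation of off-body
time — and evaluate how accurately reported energy intake (EI) tracks
measured expenditure.

Who it is for: nutrition and mHealth researchers who need the standard
EI-validation pipeline (inclusion filters, misreporting classification,
Bland–Altman agreement, accuracy regressions) as reproducible, tested
code, together with a seeded synthetic-cohort generator for method
development when participant-level data cannot be shared.

## The model in brief

For participant *i* with sex *s*, age *a* and weight *w*:

* `BMR_i = a_s,band × w_i + b_s,band` (Schofield weight-only
  coefficients, kJ/day),
* `TEE_app,i = BMR_i × PAL(s, level)` with the five-level answer mapped
  to 1.3–2.1 (girls) / 1.4–2.2 (boys),
* `TEE_SWA,i = Σ on-body minute EE + off-minutes × BMR_i/1440`,
* days with EI < 2092 kJ or wear < 19 h are excluded; per-participant
  values are means over each metric's own included days,
* reporting accuracy: `EI − TEE`, `EI/TEE`, `(EI−TEE)/TEE`; within ±5 %
  of TEE (inclusive) is *plausible*, otherwise *under*/*over*,
* agreement: Bland–Altman limits `mean(d) ± 1.96 × SD(d)`; factors are
  screened univariably, then by forward stepwise OLS
  (entry p < .05, removal p > .10).

## Worked example

```r
library(dietsense)

study <- generate_study(sim_config(seed = 42))   # 81 synthetic adolescents
res   <- run_pipeline(study)                     # intake, TEE, filters, metrics
ev    <- res$evaluations

median(ev$ei_over_tee)            # 0.767
median(ev$teeapp_over_teeswa)     # 1.179
table(ev$reporting_class)
#>     under plausible      over
#>        55         9        16

bland_altman(ev$ei_kj, ev$tee_swa_kj, ev$participant_id)
#> <bland_altman> n=80  mean diff -1892.4 (SD 3323.2)  LoA [-8405.8, 4621.1]  6 outside
```

Reading this: the synthetic cohort was generated with a group-level
reporting ratio of 0.71 and an app TEE inflated 1.19× over the armband;
the pipeline recovers both (0.767 and 1.179 on this single seed —
single-cohort medians scatter around the targets, which is why the
acceptance script averages over 20 seeds), classifies
most participants as under-reporters, and the Bland–Altman summary shows
the mean EI−TEE deficit in kJ/day with its limits of agreement.
Questionnaire scoring and the accuracy regressions continue from
`score_questionnaire()` / `accuracy_regression()`; a command-line wrapper
with `simulate`, `intake`, `tee`, `score-questionnaire` and `evaluate`
subcommands is in `inst/cli/dietsense.R`.

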