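# pareidolia

Simulation and analysis tools for divided-visual-field signal-detection
experiments on **pareidolia** — the tendency to perceive meaningful
signals (canonically faces) in visual noise. The package reconstructs a
complete psychophysics pipeline as tested, reproducible code:

1. **Stimulus synthesis** — face or flower signal images embedded in
   pink (1/f) noise by pixel-wise mixing. A signal image is placed at
   one of eight lateralised positions inside a 400 × 400-pixel grid
   (4.2° of visual angle; the signal subtends 1.57° in height), mixed
   pixel-by-pixel with a contrast-matched noise-only companion at
   prescribed noise-pixel proportions (44–50% for faces, 38–44% for
   flowers), band-pass filtered with an octave-bandwidth Gaussian
   centred on 1.5 cycles/degree (6.3 cycles per image), and held to an
   RMS contrast between 0.25 and 0.35. A full default set is 128
   composites per signal category plus 256 unique noise-only images,
   each with a machine-readable manifest row.
2. **Experiment design** — per-subject schedules of two 256-trial
   blocks (face, flower), each image unique within a block, stimuli
   lateralised to the left or right visual field, with block order,
   response mapping and responding hand counterbalanced across the
   cohort. Both the equal-ratio design (128 signal / 128 noise trials)
   and the 25/75 design (64 / 192) are supported.
3. **Simulated observers** — synthetic cohorts under an equal-variance
   signal-detection model (per-category sensitivity, per
   category × hemifield criterion, lapses, lognormal reaction times) or
   a drift-diffusion accumulator (drift proportional to signal
   strength, absorbing boundaries, hemifield-specific start-point bias,
   non-decision time), with four O-LIFE schizotypy subscale scores per
   observer and a configurable coupling between Unusual Experiences and
   face-block response bias.
4. **Signal-detection analysis** — per subject × category × hemifield
   hit and false-alarm rates with a uniform log-linear correction,
   sensitivity *d′* = z(HR) − z(FAR), response criterion
   *c* = −(z(HR) + z(FAR))/2, and correct-trial reaction-time means.
5. **Group statistics** — repeated-measures ANOVA for two-level
   within-subject designs with partial eta squared, Pearson
   correlations against trait scores with Bonferroni-adjusted alpha
   (0.0125 for four subscales), and linear regression with VIF /
   tolerance collinearity screening.
6. **Validation** — named scenarios parameterised at published
   group-level values and parameter-recovery reports (bias, RMSE,
   CI coverage) over replicate simulated cohorts.

The core quantities are the equal-variance signal-detection measures

    d' = z(HR) − z(FAR)          (sensitivity; 0 = chance)
    c  = −(z(HR) + z(FAR)) / 2   (bias; negative = liberal, "present"-prone)

estimated from corrected rates HR = (hits + ½)/(n_signal + 1),
FAR = (false alarms + ½)/(n_noise + 1).

## Worked example

Simulate a 26-subject cohort at the equal-ratio design's baseline
truths, run every observer through a full two-block schedule, and
analyse the trial logs:

```r
library(pareidolia)
library(dplyr)

spec      <- scenario("exp1-baseline")$spec
cohort    <- sample_cohort(spec, seed = 11)
manifest  <- virtual_manifest()
schedules <- bind_rows(lapply(cohort$subject_id, function(i)
  build_trial_schedule(1, i, manifest, seed = 1100 + i)))
log  <- run_cohort_experiment(cohort, schedules, seed = 12)
summ <- subject_condition_summary(log)

rm_anova(summ, dv = "dprime", within = c("category", "visual_field"))
#>   effect                  df1   df2 statistic p.value      pes estimate
#> 1 category                  1    25   11.1    0.00271 0.307     0.370
#> 2 visual_field              1    25    0.152  0.700   0.00605   0.0190
#> 3 category:visual_field     1    25    0.0174 0.896   0.000697 -0.00635
```

Sensitivity is higher for flowers than faces (group means 0.779 vs
0.410 in this cohort) with no hemifield difference — the structure the
generator injects. The criterion shows the hemifield asymmetry instead:

```r
rm_anova(summ, dv = "criterion", within = c("category", "visual_field"))
#>   effect                  df1   df2 statistic  p.value     pes estimate
#> 1 category                  1    25    4.46   4.50e- 2 0.151   -0.180
#> 2 visual_field              1    25   93.3    6.39e-10 0.789   -0.211
#> 3 category:visual_field     1    25    0.0297 8.65e- 1 0.00119 -0.00382
```

Observers are more liberal (lower *c*, more false alarms) in the right
visual field: group mean *c* = 0.368 (LVF) vs 0.157 (RVF). The
face-block bias correlates with the Unusual Experiences subscale and
with no other trait, at the Bonferroni-adjusted alpha:

```r
subj <- summ |>
  filter(category == "face") |>
  group_by(subject_id) |>
  summarise(c_face = mean(criterion)) |>
  left_join(cohort, by = "subject_id")

pearson_with_bonferroni(subj, "c_face",
                        c("UnEx", "CogDis", "IntAnh", "ImpNon"))
#>   predictor estimate p.value     n alpha_adjusted significant
#> 1 UnEx       -0.590  0.00150    26         0.0125 TRUE
#> 2 CogDis     -0.0998 0.628      26         0.0125 FALSE
#> 3 IntAnh      0.0729 0.724      26         0.0125 FALSE
#> 4 ImpNon      0.436  0.0261     26         0.0125 FALSE
```

Higher Unusual Experiences scores go with a lower (more liberal)
face-block criterion — a greater readiness to see a face in noise. The
corresponding regression is free of collinearity (max VIF 1.13,
min tolerance 0.884).

Stimuli themselves are generated with

```r
set <- build_stimulus_set(seed = 1)   # 512 images, ~1 min
set$manifest                          # one metadata row per image
plot_stimulus(set$images[[1]])
write_stimulus_set(set, "stimuli/")   # 8-bit PNGs + manifest.jsonl
```

## Package layout

- `R/` — stimulus synthesis (`generate_pink_noise`, `pixel_mix`,
  `bandpass_filter`, `build_stimulus_set`), design
  (`build_trial_schedule`, `counterbalance_cohort`), observers
  (`sample_cohort`, `run_experiment`, `ddm_closed_form`), analysis
  (`compute_rates`, `dprime`, `criterion`,
  `subject_condition_summary`), group statistics (`rm_anova`,
  `pearson_with_bonferroni`, `ols_with_vif`) and validation
  (`scenario`, `run_scenario`).
- `vignettes/pareidolia-methods.Rmd` — the models, their assumptions,
  parameter choices and known limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
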