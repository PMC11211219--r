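# aolvratio

Quantitative assessment of aortic stenosis (AS) severity from the routine
3-chamber bSSFP cine of a cardiovascular MR exam, using the **Ao:LV
ratio** — the mean blood signal in a ~1 cm² ascending-aorta region of
interest divided by the mean blood signal in an LV-cavity ROI, both on the
end-systolic frame:

```
Ao:LV = mean(S_aorta ROI) / mean(S_LV ROI)
```

Turbulent flow through a stenotic valve dephases spins within a voxel and
darkens the ascending aorta on bright-blood cines; because absolute bSSFP
signal is not comparable across scanners, the ratio normalises the void
against the patient's own LV blood pool. Lower ratios mean more severe
stenosis. Two operating cut-offs turn the ratio into a triage rule: a ratio
< 0.86 flags AS of any severity, and < 0.58 flags severe AS (values exactly
at a cut-off fall in the less-diseased class).

The package is aimed at CMR methods researchers: it provides the
measurement protocol as tested code, the cohort-level statistics used to
evaluate such a marker, and — since no patient data can ship with it — two
synthetic generators that make every stage verifiable end-to-end:

* **measurement** — end-systolic frame selection (smallest LV cavity,
  earliest on ties), rule-based ROI placement (aortic disc 10 mm above the
  valve along the aortic direction; LV disc at the cavity center), mean
  signal by a strict center-in-disc pixel rule, the ratio, and the
  severity call.
* **diagnostics** — Pearson correlation with t-transform p-values,
  Mann–Whitney ROC/AUC with seeded bootstrap CI and Youden cut-off
  (orientation: lower ratio = positive), sensitivity/specificity at fixed
  cut-offs, one-way ANOVA with Tukey HSD, stratified subgroup comparisons
  (valve morphology, flow state, root dilation), and observer agreement
  (ICC(2,1), Bland–Altman, inter/intra-reader Pearson).
* **synthetic cohort** — truncated-normal, Gaussian-copula patient
  generator whose defaults reproduce the published study conditions
  (group sizes 86/66/78/84; severity-conditional ratios 1.01 ± 0.19,
  0.83 ± 0.14, 0.67 ± 0.13, 0.45 ± 0.12; TTE covariates and subgroup
  fractions per group).
* **phantom** — a 2-D + time cine phantom with contracting LV, myocardial
  ring and an aortic band painted at `blood_signal × true_ratio`
  (phenomenological flow void), optional Rician noise, and NIfTI +
  landmark-JSON writers.
* **study orchestration** — `run_study()` chains everything into a
  deterministic, seeded JSON report with Monte-Carlo standard errors; a
  thin CLI (`inst/cli/aolv.R`) exposes `simulate`, `render-phantom`,
  `measure`, `analyze` and `run` subcommands.

## Worked example

Measure a phantom whose ground-truth ratio is 0.36, then evaluate the
marker on a synthetic cohort:

```r
library(aolvratio)

ph <- render_phantom(phantom_spec(true_ratio = 0.36))
m  <- measure_cine(ph$cine, ph$landmarks)
m
#> Ao:LV ratio: 67.0 / 186.2 = 0.36 (frame 9)
as.character(m$class)
#> [1] "severe_AS"
```

The measured aortic mean (67.0) over the painted LV blood signal (186.2)
recovers the ground-truth ratio exactly on the noise-free phantom, and
0.36 < 0.58 calls severe AS. On a cohort:

```r
coh <- generate_cohort(cohort_preset("1.5T"), seed = 42)
aggregate(ao_lv_ratio ~ severity, coh, function(x) round(c(mean = mean(x), sd = sd(x)), 2))
#>   severity ao_lv_ratio.mean ao_lv_ratio.sd
#> 1  control             1.02           0.20
#> 2     mild             0.82           0.14
#> 3 moderate             0.66           0.13
#> 4   severe             0.45           0.12

roc <- roc_analysis(coh$ao_lv_ratio, coh$severity != "control", seed = 1)
roc
#> ROC (lower ratio = positive): AUC = 0.909 (95% CI 0.867-0.945), Youden cutoff = 0.842
round(sens_spec_at_cutoff(coh$ao_lv_ratio, coh$severity != "control", 0.86), 3)
#> sensitivity specificity
#>       0.860       0.814
round(sens_spec_at_cutoff(coh$ao_lv_ratio, coh$severity == "severe", 0.58), 3)
#> sensitivity specificity
#>       0.881       0.870
```

One seeded cohort drawn from the calibrated group distributions gives an
any-AS AUC of 0.909 and operating-point sensitivities/specificities in the
mid-80s to low-90s — single-replicate values that scatter around the
published figures (AUC 0.91; 84%/82% at 0.86; 83%/92% at 0.58).

See `vignettes/aolv-ratio-methods.Rmd` for the measurement model, the
generator calibration choices and the numerical conventions.

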