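---
title: "The Ao:LV signal ratio: measurement model, synthetic calibration and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Ao:LV signal ratio: measurement model, synthetic calibration and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aolvratio)
```

## The measurement

Turbulent, accelerated flow through a stenotic aortic valve dephases spins
within a voxel and appears on bright-blood bSSFP cine images as a signal
void in the ascending aorta. Absolute bSSFP signal is not comparable across
scanners, vendors or field strengths, so the quantity of interest is a
*ratio*: the mean blood signal in a ~1 cm^2 region of interest (ROI) in the
ascending aorta divided by the mean blood signal in an LV-cavity ROI, both
read off the same end-systolic frame of a routine 3-chamber cine,

$$\mathrm{Ao{:}LV} = \frac{\bar S_{\mathrm{Ao}}}{\bar S_{\mathrm{LV}}}.$$

The more severe the stenosis, the deeper the aortic void and the lower the
ratio. Two operating cut-offs on this scale, 0.86 for stenosis of any
severity and 0.58 for severe stenosis, turn the ratio into a triage rule; a
patient is called positive when the ratio is *strictly below* the cut-off,
so a value exactly at a cut-off falls in the less-diseased class.

`aolvratio` implements this protocol as code: deterministic end-systolic
frame selection, rule-based ROI placement, mean-signal extraction, the
ratio, the severity call, and the cohort-level statistics used to evaluate
the marker. Because no patient images ship with the package, two generators
make every stage testable: a cine *phantom* with a known painted ratio, and
a *synthetic cohort* whose group-conditional ratio distributions are
calibrated to published values.

## Measurement protocol and its operationalisation

Three rules in the clinical protocol needed a precise operational form:

* **End-systole.** Observers identify it visually as the frame with the
  smallest LV cavity after aortic valve closure. The package determines it
  from the per-frame LV cavity masks: the frame minimising mask area
  (pixel count x pixel area), ties broken by the earliest frame. Valve
  timing is not modelled; the mask argmin is the whole rule.
* **ROI geometry.** "Approximately 1 cm above the leaflets" is fixed at
  exactly 10 mm along the annotated aortic direction from the valve point;
  the LV ROI sits at the annotated cavity center. Both ROIs are discs of
  nominal area 1 cm^2 (radius $\sqrt{100/\pi} \approx 5.64$ mm).
* **Pixel inclusion.** A pixel belongs to an ROI iff its center lies
  strictly inside the disc. This rule is trivially checkable against
  exhaustive enumeration and its area converges to the nominal area as the
  grid refines. At 0.8 and 1.46 mm spacing the achieved area is within 10%
  of 1 cm^2; at 2 mm it can fall ~16% short for grid-aligned centers. The
  achieved area is recorded on each ROI, and the measured *ratio* is
  unaffected on uniform blood pools, which is why recovery remains exact at
  coarse spacing.

Placement is validated, not silently accepted: a disc extending beyond the
image, or an LV disc with any pixel outside the cavity mask (myocardial or
papillary contamination), raises an error naming the offending ROI.

Coordinates are (row, col) in mm with the first pixel center at (0, 0);
frame indices are 1-based in the R API. The on-disk landmark JSON schema is
0-based and documents both conventions explicitly.

## The cine phantom

The phantom is a 2-D + time cartoon of the 3-chamber view, matching the
single-slice acquisition: an elliptical LV cavity inside a myocardial ring,
and an ascending-aorta band of constant width starting at the valve point.
The cavity semi-axes scale by $1 - f\,(1 + \cos(2\pi (t - t_{ES})/n))/2$,
so the area minimum falls exactly on the configured end-systolic frame and
the frame selector can be checked against ground truth.

The flow void is modelled *phenomenologically*: the aortic lumen is painted
at `blood_signal * true_ratio`. No intravoxel-dephasing physics, bSSFP
off-resonance banding or papillary muscles are simulated — the void enters
the analysis only as an observed intensity effect, so a multiplicative
attenuation with known ground truth is the right level of abstraction for
validating the measurement chain. Noise, when enabled, is Rician
($\sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim N(0,\sigma)$), the correct model for
magnitude MR images; at high SNR it coincides with Gaussian noise, and its
analytic mean (a Laguerre-function expression) serves as the oracle for
noisy-recovery tests.

Defaults: 128 x 128 pixels at 1.46 x 1.46 mm (a typical 1.5 T cine
resolution), 25 frames at 36.5 ms, LV blood at 186.2 intensity units (the
LV mean of the package's worked example), myocardium 80, background 10,
aortic band 28 mm wide and 40 mm long so the 10 mm-offset ROI always fits
with margin.

## The synthetic cohort

The generator's defaults *are* the study conditions: group sizes 86
control / 66 mild / 78 moderate / 84 severe, and severity-conditional
Ao:LV ratios drawn from normals with mean +/- SD of 1.01 +/- 0.19,
0.83 +/- 0.14, 0.67 +/- 0.13 and 0.45 +/- 0.12. TTE covariates (peak
velocity, dimensionless index, valve area, stroke volume index) use the
published per-group baseline means and SDs, and subgroup fractions
(bicuspid valve, dilated root) use the published per-group counts.

Design choices the published summary statistics do not determine:

* **Truncation.** Only mean +/- SD are published, but ratios and
  velocities are physically positive, so marginals are normals truncated
  below at `truncation_floor` (default 0.05). At the calibrated parameters
  the truncated mass is negligible (< 1e-6), so the truncation protects
  edge configurations without distorting the calibrated moments.
* **Within-group coupling.** The overall ratio-velocity correlation
  (r ~ -0.8) exceeds what between-group separation alone produces, so some
  within-group dependence must exist, but its strength is not published.
  Ratio and velocity are coupled through a Gaussian copula with default
  correlation -0.5, a calibration choice that reproduces an overall
  correlation near the published value; it is exposed as
  `within_group_coupling` and all diagnostic-accuracy results are
  insensitive to it (AUC and sens/spec depend only on the marginals).
* **Gradient coherence.** Peak gradient follows the simplified Bernoulli
  relation $\Delta P_{peak} = 4v^2$ plus N(0, 2 mmHg) noise, and mean
  gradient is the group-specific published mean:peak proportion of peak
  gradient plus N(0, 2 mmHg); the published group moments are consistent
  with this relation, and it keeps each record's TTE fields mutually
  consistent rather than independently sampled.
* **Low flow is derived, not sampled.** `low_flow` is defined as stroke
  volume index <= 35 ml/m^2 applied to the sampled SVi, preserving the
  defining invariant exactly; the implied low-flow prevalence is close to,
  but not exactly, the published counts.
* **Morphology offsets.** Published morphology-stratified means suggest
  bicuspid patients may run slightly lower in the control group, but no
  generative mechanism is published. The generator exposes an optional
  per-group `bicuspid_ratio_offset` (default 0, i.e. the null) so that
  morphology-dependent means can be emulated when wanted.
* **3 T preset.** No per-group 3 T distributions are published, only that
  separation weakens. The `"3T"` preset is an explicit stand-in: the 1.5 T
  ratio means shrunk towards their grand mean by a configurable factor
  (default 0.5).
* **Group sizes.** The published per-field-strength group breakdown is not
  available (the 3 T subset totals 67 without a printed split), so the
  default preset uses the overall group sizes.

What the generator does *not* emulate: echo measurement error, the
CMR-TTE interval, scanner-vendor intensity idiosyncrasies, and any image
content (patients are rows, not pixels). Passing cohort-level tests
therefore demonstrates that the statistics are implemented correctly and
that the printed group distributions imply the printed diagnostic
accuracy — not that the ratio performs identically on any particular
scanner's images.

## Diagnostics: conventions and numerics

* **ROC orientation.** The diseased class has *lower* ratios. This is
  implemented by thresholding with `<` (not by negating scores), matching
  the cut-off phrasing.
* **AUC.** Mann-Whitney concordance with ties counted 1/2, computed via
  the rank identity; the trapezoidal integral of the empirical ROC equals
  it to machine precision, which the tests assert.
* **AUC confidence interval.** A seeded nonparametric percentile bootstrap
  over patients (default 2000 replicates). The published CI method is
  unstated; the bootstrap makes the fewest distributional assumptions.
  Degenerate single-class resamples (vanishingly rare at these group
  sizes) are dropped.
* **Youden cut-off.** Maximises sensitivity + specificity - 1; ties
  resolve to the higher-specificity (lower) threshold.
* **ANOVA / Tukey.** `stats::aov` and `stats::TukeyHSD` (studentized
  range); with two groups the Tukey-adjusted p equals the pooled-variance
  t-test p via $q = \sqrt2\,|t|$, an equivalence the tests exploit. No
  additional multiplicity layer is applied beyond Tukey.
* **ICC.** The model is fixed to ICC(2,1) — two-way random effects,
  absolute agreement, single measure — computed from the mean-squares
  decomposition; "ICC" alone is ambiguous and the absolute-agreement form
  is the conservative choice for a measurement method (a constant reader
  offset lowers it while leaving Pearson r at 1).
* **Bland-Altman.** Bias is mean(reader2 - reader1), limits of agreement
  bias +/- 1.96 SD of the differences.
* **Pearson p-values.** Two-sided, from the t-transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ on n - 2 df (`stats::cor.test`).
* **Degenerate inputs.** Constant correlation inputs, single-class labels,
  empty masks, non-positive LV means and empty stratification cells are
  all defined behaviours: the first four are errors naming the offending
  quantity; an empty cell is flagged absent, not an error.

## The orchestrated study

`run_study()` chains the pipeline: replicate cohorts, per-replicate AUC
and operating-point metrics, aggregation as mean with Monte-Carlo standard
error (so every tolerance in downstream use is explicit), plus — on the
first replicate — the bootstrap CI, the ANOVA/Tukey table, the three
stratified subgroup tables, and a simulated dual-reader agreement block
(`observer_sigma`, default 0.06 ratio units, chosen so inter-reader
correlations land in the published 0.91-0.95 range; a calibration choice,
since per-reader noise is not published). Replicate r uses seed
`seed + r`; reports are byte-identical for a fixed seed, and stage wall
times are logged but never written into the report.

Problem sizes in the shipped tests and acceptance script — 200 cohort
replicates of 314 patients, 100 noisy phantoms, 10,000-per-group
convergence checks — were chosen so Monte-Carlo standard errors are an
order of magnitude below the tolerances being asserted while a full run
completes in well under a minute on a laptop core.

## Known limitations

* The phantom validates the measurement *chain*, not observer behaviour:
  landmarks are exact, whereas clinical ROI placement is manual. Automatic
  landmark detection is explicitly out of scope.
* The cohort generator reproduces first- and second-order group structure
  only; real inter-scanner and inter-vendor effects enter solely through
  the ratio's variance.
* The 3 T preset encodes the *direction* of the field-strength effect, not
  its measured size.
* DICOM I/O is not provided; NIfTI + landmark JSON is the interchange
  format.
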