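---
title: "Methods: repeatability-informed lesion phenotyping and normative z-score mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability-informed lesion phenotyping and normative z-score mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters, what the
synthetic-data generators do and do not emulate, the numerical choices,
and the design decisions taken where the methodology left room.

```{r setup}
library(rimla)
```

## 1. The longitudinal model and its assumptions

A lesion's volume trajectory is modelled as a straight line in time,
$v_i(t) = \beta_i^0 + \beta_i^1 t + \varepsilon$, observed through a
segmentation whose measurement error is proportional to the measured
volume. The proportionality constant is the scan-rescan coefficient of
variation (COV): the sample SD over the mean of repeated volume
measurements of the same lesion, averaged (unweighted) across lesions.
The COV is estimated once, on scan-rescan data, from lesions detected in
every scan and with all volumes inside the 3-150 µL analysis window.

RIMLA propagates this repeatability into the slope inference. Per lesion
and timepoint, 100 synthetic volumes are drawn from
$N(v_i(t),\ \mathrm{COV}\cdot v_i(t))$; 100 bootstrap regressions are then
fitted, each sampling one synthetic observation per timepoint (with
replacement across bootstrap replicates). A lesion is *enlarging*
(*shrinking*) when at least 95 % of bootstrap slopes are positive
(negative) — the threshold is inclusive, so 95/100 qualifies — and
*stable* otherwise. The bootstrap p value is the opposite-sign fraction,
$1 - \max(\widehat{F}_{>0}, \widehat{F}_{<0})$; no closed-form p is
assumed. Lesions detected only at the last timepoint are *new* (no slope
is fitted), and any other incomplete series is *discarded*.

Assumptions worth stating explicitly:

- measurement noise is Gaussian with SD proportional to the *measured*
  volume at each timepoint (the observed value stands in for the truth);
- timepoints are independent given the trajectory; there is no
  within-lesion serial correlation of segmentation errors;
- the volumetric trend is linear over the observation window;
- the same global mean COV applies to every lesion regardless of size,
  location or contrast.

With 100 bootstrap samples the sign-fraction test is discrete: under a
true zero slope the nominal one-sided rate of 5 % can be exceeded
slightly, which is why the calibration tests allow up to 8 % per side
rather than exactly 5 %.

### Units and scale behaviour

Slopes are in µL/day; times are stored in days (visit intervals in the
longitudinal setting are naturally reported in days) and per-year slopes
are a simple rescaling, which the bootstrap respects exactly. Because the
noise model is multiplicative, the whole procedure is scale invariant:
multiplying all volumes of a series by a positive constant leaves every
label unchanged and rescales the slopes by the same constant. The test
suite asserts both properties exactly.

### Per-lesion random streams

Each lesion's synthetic draws and bootstrap resamples use a random stream
derived from (master seed, lesion rank in sorted id order), so results are
independent of the row order of the input table and of which other lesions
happen to be processed in the same call.

## 2. The normative model

For each modality X ∈ {T1, T2, T2/T1} and each voxel, an ordinary
least-squares regression

$$E\{X\} = \beta_0 + \beta_{sex}\,sex + \beta_{age}\,age_c + \beta_{age^2}\,age_c^2$$

is fitted on the healthy cohort, with sex binary (1 = male) and age
centred at the cohort mean (37.3 years in the reference cohort the
defaults emulate; centring reduces the collinearity of the linear and
quadratic age terms). The normative spread is the voxelwise residual SD
with denominator $n-4$. The methodology the field uses does not restate
the spread estimator; the residual SD is the canonical choice and has the
testable consequence that held-out healthy subjects drawn from the same
population have z-scores with mean 0 and SD 1 (up to the
degrees-of-freedom inflation $\sqrt{(n-4)/(n-6)}$ visible at small $n$).
Patient deviation maps are $z = (x - E\{X\})/\sigma$; voxels with
$\sigma < 10^{-6}$ (native units) or a rank-deficient design are flagged
invalid and propagate as missing values, never as zeros.

z-scoring is equivariant under a change of modality units (rescaling a
modality rescales expectation and spread identically), which the tests
assert; it is *not* invariant to registration errors — spatial
normalisation is assumed done upstream, and the package only retains the
mutual-information QC step: subjects whose joint-histogram mutual
information against the template falls below the cohort's 5th percentile
(linear interpolation) are flagged. Mutual information uses 64 equal-width
bins over the jointly finite range by default; equal-count binning is
available and makes the estimate invariant to monotone intensity
rescalings.

## 3. Lesion geometry

Distances are Euclidean in millimetres, honouring anisotropic voxel
dimensions (the reference acquisition is 0.7 × 0.7 × 3.0 mm for T2
mapping), computed with an exact separable lower-envelope distance
transform in C++ and cross-checked in the tests against a brute-force
pairwise oracle on random scenes.

Ring conventions, decided once and applied everywhere: ring 1 is
$0 < d < 2$ mm from the lesion border, ring 2 is $2 \le d < 3.5$ mm —
"below 2 mm and below 3.5 mm" makes the upper bounds strict, and ring 2's
closed lower bound closes the gap. The volume filter is the closed
interval $[3, 150]$ µL, since only strict violations ("smaller than",
"larger than") are excluded. A voxel within 3.5 mm of two or more distinct
lesions is removed from all rings; the outer ring cutoff is the only
spatial scale in scope, so it also serves as the exclusivity radius. The
deep-white-matter restriction erodes the white-matter/subcortical region
by one voxel (26-connectivity) and keeps only lesions entirely inside the
eroded region. Connected-component labelling defaults to 26-connectivity
and orders labels by the first voxel in scan order, making labelling
deterministic.

## 4. Feature extraction and statistics

Eighteen metrics per lesion: mean and sample SD (denominator $n-1$) of the
z-scores in {lesion, ring 1, ring 2} × {T1, T2, T2/T1}. Regions with fewer
than two valid voxels yield missing metrics rather than degenerate zeros;
the row is retained and flagged.

The class effect on each metric is tested with the classical aligned-rank
construction: subtract the additive least-squares estimates of the
nuisance effects (patient and disease course), rank the aligned values
with mid-ranks for ties, and run a fixed-effects ANOVA on the ranks with
the same factors; the reported effect size is the partial
$\eta^2 = SS_{class}/(SS_{class}+SS_{resid})$ on the ranked response.
Patients are nested in disease course, so the two factors are partially
aliased; aliased columns are dropped from the least-squares estimate
(coefficients set to zero), which is the standard behaviour of linear
model fitting and leaves the class test unaffected. Interactions are not
modelled: only main fixed effects are named by the analysis this package
reproduces. With a single patient and a single disease course the
procedure provably reduces to a one-way ANOVA on plain ranks, and the
tests assert that reduction against `anova(lm(...))` as an oracle.
Post-hoc comparisons are rank-sum tests between all class pairs on the
aligned-ranked response; all multiple-comparison corrections use Holm
step-down (`stats::p.adjust`). RR-vs-SP comparisons use the two-sided
rank-sum test with tie-corrected normal approximation.

## 5. Classification and agreement

The multivariate analysis trains a random forest in which *every tree* is
grown on its own balanced bootstrap draw: 1000 lesions per tree, 250 per
class drawn with replacement, whatever the training prevalences. The
implementation grows each tree on an explicit balanced draw and combines
them, because the stratified-sampling interface of the underlying forest
library refuses per-stratum draws larger than the stratum, which would
silently break the 25 %-per-class contract for rare classes. The split is
3000 training / remaining test lesions by default (redrawn until every
class is present in both partitions); on smaller scenes the pipeline falls
back to an 80/20 split.

Reported metrics are kept separate and named precisely, because "overall
accuracy estimated using the multiclass area under the curve" conflates
two notions: plain accuracy, per-class one-vs-rest balanced accuracy
(mean of recall and specificity), and the pairwise-average (Hand–Till)
multiclass AUC, in which each unordered class pair contributes the mean of
its two one-directional rank AUCs. Krippendorff's alpha (nominal metric)
is computed from the coincidence matrix of truth and prediction, with a
one-sided permutation p value (default 10⁴ permutations of the predicted
labels) since no analytic null is assumed. Variable importance is the drop
in held-out accuracy when one feature column is permuted, averaged over 50
permutations (the evaluation set is configurable; held-out data is the
default as the less optimistic choice). Collinearity is quantified by
variance inflation factors $1/(1-R_j^2)$; perfectly collinear predictors
are reported as infinite rather than raising an error.

## 6. What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes:

- **healthy cohorts**: each voxel follows the additive age/sex model plus
  i.i.d. Gaussian noise, so the atlas fit is correctly specified and
  plant-and-recover tests are exact at zero noise;
- **patient cases**: a three-label head model (background, a 2-voxel
  cortical band, white matter + subcortical interior — the band exists to
  exercise the restriction filter), with spherical lesions whose voxelwise
  z-scores follow $N(\mu_{class}, s_{class})$ in the core and
  $N(\mu_{ring1}, s_{class})$ in the first ring. Default class targets are
  the published per-class medians (lesion-core T1 z: stable 4.33,
  shrinking 3.97, enlarging 3.84, new 2.77; spreads 1.92/1.33/1.51/0.98),
  and default prevalences are 62.4/14.6/12.1/10.9 %;
- **volume series**: linear true trajectories (default slopes 0 and
  ±0.5 µL/day over four semi-annual visits), multiplicative Gaussian noise
  at COV 0.17, truncated below 0.5 µL; *new* lesions appear only at the
  last visit;
- **scan-rescan tables**: repeated draws at the same COV;
- **feature tables**: per-class metric distributions matched to the
  published medians and IQRs (normal with $\sigma = IQR/1.349$,
  SD metrics resampled positive, volumes kept in-window), nested in
  patients with an RR/SP split matching a 251/32 cohort.

Negative draws are always handled by resampling, not clipping, so the
noise model stays unbiased near zero. What the generators deliberately do
*not* emulate: MR physics (bias fields, partial volume, motion),
registration error, spatially correlated noise, non-spherical lesion
shapes, within-patient spatial clustering of lesions, and any correlation
between a lesion's microstructural profile and its longitudinal class
beyond the planted class contrasts. Passing tests therefore demonstrate
that the *procedures* are correct and calibrated under their stated
assumptions — not that the assumptions hold on scanner data.

## 7. Numerical choices and degenerate inputs

- Distance-transform and labelling code paths are exact; cutoff
  comparisons use strict/closed bounds as specified above, and voxels
  lying numerically on a cutoff are resolved by floating point — the test
  oracles skip such voxels explicitly.
- A noise-free cohort yields $\sigma = 0$: those voxels are flagged
  invalid, and z-scoring returns missing values rather than dividing by
  zero.
- `t2t1_ratio` returns missing where T1 ≤ 0; `vif` returns `Inf` for
  aliased predictors; `qc_pass` with one subject passes it (the threshold
  equals the value and failure requires strict inequality).
- Holm adjustment, rank-sum tests, quantiles (type 7) and the ANOVA
  building blocks delegate to base R.
- All generators and fits are deterministic under a fixed seed;
  sub-streams are derived as `(seed * 48271 + 7919 * index) mod 2^31 - 19`
  to keep them valid 32-bit integers.

## 8. Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to keep the
statistics meaningful: calibration of the stable-lesion false-change rate
uses 1000 series of five visits; slope recovery uses 400 series at
±0.5 µL/day; normative calibration fits 50 and holds out 40 subjects on a
12³ grid (≈ 2 × 10⁵ pooled z values); the geometry oracle covers 25 random
scenes up to 25³ including anisotropic voxels; the aligned-rank null is
checked over 500 replicates of 200 lesions; and the end-to-end scene runs
12 patients × 4 lesions on a 48³ grid twice to assert bit-identical
manifests. The acceptance script additionally builds a 3264-lesion
feature cohort with the published 3000/264 split.

## 9. Known limitations

- The COV estimate inherits the downward bias of the sample SD at four
  scans (factor ≈ 0.92); the method defines repeatability through this
  estimator, so the package reproduces the bias rather than correcting it.
- The aligned-rank ANOVA treats patients as fixed effects; a
  random-intercept formulation is out of scope by design.
- Voxelwise expansion mapping (deformation-based detection of slowly
  expanding lesions) is out of scope; RIMLA is volumetric only.
- The multiclass AUC construction is one of several in use; the
  pairwise-average form is implemented and named in the report metadata.
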