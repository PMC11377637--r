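# rimla

Repeatability-informed longitudinal assessment of multiple sclerosis (MS)
lesions, with quantitative-MRI normative mapping.

## What problem this package addresses

Serial MRI of MS patients shows lesions that enlarge, shrink, appear or stay
stable over time, and these longitudinal phenotypes carry prognostic
information (slowly expanding lesions in particular). Deciding whether an
individual lesion truly changed volume is hard, because the automated
segmentations that produce the volumes are themselves noisy: the same lesion
segmented on a scan-rescan pair can differ by 10-20 % in volume. This package
implements, for researchers working with co-registered quantitative MRI:

- **RIMLA** (repeatability-informed method for longitudinal assessment): a
  bootstrap slope analysis that propagates the scan-rescan repeatability of
  the segmentation into the decision *enlarging / shrinking / stable / new*
  for every lesion;
- **voxelwise normative atlases** of quantitative T1, T2 and T2/T1 values,
  fitted on a healthy cohort as a function of age and sex, and the z-score
  deviation maps they induce for patients;
- **perilesional ring geometry**: exact anisotropic Euclidean distance
  transforms, two exclusive rings per lesion (below 2 mm and below 3.5 mm
  from the lesion border), multi-lesion exclusion, the 3-150 uL volume
  window and the deep-white-matter restriction;
- the downstream **statistics**: 18 z-score metrics per lesion (3 modalities
  x 3 regions x mean/SD), aligned-rank-transform ANOVA across lesion classes
  with patient and disease-course fixed effects, Holm-corrected post-hocs,
  RR-vs-SP Wilcoxon comparisons, a balanced random forest with permutation
  variable importance, Krippendorff's alpha, pairwise multiclass AUC and
  variance inflation factors;
- a **synthetic-data module** that generates healthy cohorts, patient cases
  with planted lesions, longitudinal volume series and scan-rescan tables
  with the exact statistical structure the analysis assumes, so the entire
  pipeline is testable without any patient data.

## The model at the core

For each lesion *i* with volume measurements *v_i(t)* (uL, times in days),
RIMLA first estimates the segmentation repeatability from scan-rescan data
as the mean coefficient of variation across lesions, COV = mean(sd/mean),
restricted to lesions detected in all scans with volumes in [3, 150] uL.
Then, per lesion:

1. draw 100 synthetic volumes per timepoint from N(v_i(t), COV * v_i(t)),
   resampling non-positive draws;
2. refit the regression v̂_i(t) = b0_i + b1_i t 100 times, each time
   sampling one synthetic observation per timepoint (bootstrap);
3. label the lesion **enlarging** (**shrinking**) when at least 95 % of the
   bootstrap slopes are positive (negative), **stable** otherwise, with the
   bootstrap p value `1 - max(frac > 0, frac < 0)` against H0: b1_i = 0.
   Lesions detected only at the last timepoint are **new**; other
   incomplete series are **discarded**.

Microstructure is characterized against a voxelwise normative model fitted
on healthy subjects by ordinary least squares,

    E{X} = b0 + b_sex * sex + b_age * age_c + b_age2 * age_c^2,

with X in {T1, T2, T2/T1}, sex binary (1 = male) and age centred at the
healthy-cohort mean; patient deviation maps are z = (x - E{X}) / sigma with
sigma the voxelwise residual SD.

## Worked example

```r
library(rimla)

cfg <- synth_config(seed = 42)               # study-condition defaults
sr  <- gen_scan_rescan(cfg, 200, seed = 7)   # scan-rescan volume table
cov_hat <- compute_cov(sr)$mean_cov
ser <- gen_lesion_series(cfg, 50, seed = 42) # longitudinal volume series
fit <- rimla(ser, cov = cov_hat, seed = 1)
print(fit)
```

```
RIMLA: 50 lesion series, COV 0.159, 100 synthetic draws x 100 bootstraps

enlarging shrinking    stable       new discarded 
        6         8        23        13         0 
```

The per-lesion table carries the fitted median slope (uL/day), intercept
and bootstrap p value; `new` lesions have no slope by construction:

```r
head(fit$fits, 5)
```

```
  lesion_id     label median_slope intercept bootstrap_p
1     L0001       new           NA        NA          NA
2     L0002       new           NA        NA          NA
3     L0003    stable   0.07042285 104.48527        0.07
4     L0004 enlarging   0.40374112  68.18432        0.00
5     L0005 shrinking  -0.12517252  53.65285        0.00
```

Against the generator's ground truth, 98 % of these 50 series receive the
correct label. The estimated COV (0.159) sits slightly below the generating
0.17 because the sample SD of four repeated scans is a downward-biased
estimate of the true spread -- a property of the estimator itself, which
the package reproduces faithfully.

`run_pipeline(pipeline_config(seed = 1), "out/")` runs the whole chain --
simulation, rings, atlas, z-scores, RIMLA, features, aligned-rank ANOVA,
balanced random forest -- and writes every stage output plus a manifest
with checksums; reruns under the same configuration are bit-identical.

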