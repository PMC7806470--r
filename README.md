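# strokeseg

Voxel-wise segmentation of acute ischemic stroke lesions from paired
quantitative diffusion (ADC) and T2-weighted (T2W) MRI, for preclinical
(rodent middle-cerebral-artery occlusion) and clinical imaging groups who
need objective, repeatable lesion volumes without manual region drawing.

## The method

Acute ischemic tissue has a distinctive two-channel signature: cytotoxic
edema restricts water diffusion (ADC falls below roughly
600 × 10⁻⁶ mm²/s while normal parenchyma sits near 500–1100), and
developing vasogenic edema raises the T2W signal. `strokeseg` implements a
two-stage framework that turns this signature into a segmentation model
without any manual labels:

1. **Unsupervised label generation.** The in-brain voxels of all training
   subjects are pooled into a population dataset of (ADC, T2W) observations
   and z-scored per channel. A Gaussian mixture model with K components and
   full covariances is fitted by seeded EM for each K in a scan range
   (default 2–8). In each fit the *stroke component* c\* is the one whose
   un-normalized member means show the ischemic signature — the argmax over
   components of μ_T2W,k ⁄ μ_ADC,k (reduced ADC, elevated T2W). Because
   surgery affects only one hemisphere, the contralateral hemisphere is a
   lesion-free negative control: the *contralateral stroke fraction* — the
   share of the stroke cluster lying contralateral — measures how much the
   stroke cluster leaks into tissue known to be healthy. K\* is the smallest
   K at which this fraction stops improving by more than ε (default 0.01);
   beyond it, extra components only subdivide the stroke cluster.

2. **Supervised generalization.** The mixture's hard labels are collapsed to
   binary stroke / non-stroke (everything outside c\* is non-stroke) and a
   random forest — 100 trees, both features available at every split,
   minimum leaf size 1 — is trained on the un-normalized voxel features. For
   an unseen subject the forest's vote fraction gives a per-voxel stroke
   probability map, binarized at 0.5 by default. For transfer to another
   scanner or species, where T2W (non-quantitative) is not comparable across
   instances, a variant classifier uses per-subject T2W z-scoring
   (`instance_t2w`), which is exactly invariant to affine intensity shifts;
   ADC, being quantitative, always passes through raw.

The package also provides the two classical thresholding baselines the
framework is compared against (stroke iff ADC < 680 × 10⁻⁶ mm²/s; stroke iff
T2W > 125 % of the contralateral-hemisphere mean), the full evaluation
battery (confusion-matrix metrics, Dice similarity coefficient, Matthews
correlation coefficient, lesion volumes and ratios, Pearson volume
correlations, joint probability maps, 3-D median-filter post-processing),
and a seeded synthetic phantom generator so the entire framework can be
exercised end-to-end without any data download.

## Worked example

A full experiment on a synthetic cohort with both confounders enabled — a
vasogenic edema rim (high T2W, normal ADC) around the core and a
contralateral low-ADC artifact with normal T2W:

```r
library(strokeseg)
config <- pipeline_config(
  phantom = phantom_config(include_edema = TRUE, include_artifact = TRUE),
  seed = 42)
result <- run_pipeline(config, quiet = TRUE)
print(result)
#> pipeline_result: 12 train / 20 test subjects, K* = 4
#> median per-subject metrics vs planted core:
#>  method       DSC       MCC         FPR
#>   ADCth 0.4787443 0.5407837 0.069743544
#>      ML 0.9392580 0.9376724 0.002544132
#>   T2Wth 0.3388606 0.3967067 0.104228023
```

The model-order scan shows the contralateral stroke fraction dropping until
the mixture isolates the artifact cluster at K = 4, then flattening — the
plateau rule stops there:

```r
print(result$scan)
#> model_order_scan (eps = 0.01 ): chosen K* = 4
#>  K   fraction      init converged   ok
#>  2 0.09267131  kmeans++      TRUE TRUE
#>  3 0.08015913 insertion      TRUE TRUE
#>  4 0.04412551 insertion      TRUE TRUE
#>  5 0.04927842 insertion      TRUE TRUE
#>  6 0.05043417 insertion      TRUE TRUE
#>  7 0.05075386 insertion      TRUE TRUE
#>  8 0.05063402 insertion      TRUE TRUE
```

Both thresholding baselines overestimate the lesion badly — the ADC cutoff
swallows the artifact and the healthy low-ADC tail, the T2W rule swallows
the edema rim — while the learned model tracks the planted core volume
(~51 mm³ here):

```r
aggregate(volume_mm3 ~ method, result$volumes, median)
#>   method volume_mm3
#> 1  ADCth   155.0625
#> 2     ML    51.6875
#> 3  T2Wth   205.4062
round(sapply(result$correlations, function(x) x$r), 4)
#>     ML  ADCth  T2Wth
#> 0.9964 0.9597 0.9955
```

Every stage is also callable on its own (`generate_cohort()`,
`to_feature_table()`, `make_recipe()`, `select_model_order()`,
`train_classifier()`, `predict_subject()`, `adc_threshold()`,
`confusion_metrics()`, …), real data enters through `load_subject()` from
NIfTI volumes, and `inst/cli/strokeseg.R` exposes the pipeline as a shell
command (`simulate | label | train | predict | threshold | evaluate |
run-all`).

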