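---
title: "Two-stage stroke segmentation from ADC/T2W MRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage stroke segmentation from ADC/T2W MRI: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical model behind each stage, the tunable parameters and why
their defaults are what they are, what the synthetic phantoms do and do not
emulate, and the design decisions taken where more than one defensible
choice existed.

## The voxel model

Each in-brain voxel is one observation with two features: the apparent
diffusion coefficient (ADC, stored in units of 10⁻⁶ mm²/s so that a
clinical cutoff of 680 × 10⁻⁶ mm²/s is simply the number 680) and the
T2-weighted intensity (T2W, arbitrary units). Acute ischemia pushes these
in opposite directions — cytotoxic edema lowers ADC, vasogenic edema raises
T2W — so stroke tissue occupies a distinct corner of the feature plane. The
framework is strictly voxel-wise: no spatial features, coordinates or
neighborhood statistics enter either stage, so prediction is a pure
function of a voxel's (ADC, T2W) pair after normalization. Spatial context
appears only in the optional median-filter post-processing step.

### Stage 1: mixture labeling

The pooled training voxels are z-scored per channel (`population_zscore`)
because EM on full-covariance Gaussians is not scale-equivariant in
practice when one channel spans hundreds of units and the other tens. A
K-component bivariate Gaussian mixture is then fitted by EM. The stroke
component c\* is selected as

argmax over k of μ_T2W,k ⁄ μ_ADC,k

where the μ are the means of each component's member voxels in *raw*
(un-normalized) units, so the selection is invariant to whatever affine map
produced the fitting space. The functional form of this score is a
package decision: the direction — reduced ADC together with elevated T2W —
is what defines the stroke cluster, and any score monotone in that
direction would do; `select_stroke_component()` therefore also offers the
equivalent `adc_over_t2w` ordering and a `lexicographic` fallback. Exact
ties break to the lowest component index, empty components are excluded
with a warning, and a component with non-positive mean ADC is an error
rather than a silent winner.

### Model order: the contralateral fraction

Because the occlusion is unilateral, the contralateral hemisphere is a
lesion-free negative control. The *contralateral stroke fraction* — the
share of stroke-cluster voxels lying contralateral — therefore measures
label leakage into tissue known to be healthy. The scan fits K = 2 … 8 and
chooses the smallest K whose fraction improves by less than ε = 0.01
(absolute) at the next step.

Two details matter here:

* **The denominator.** The fraction is computed over the stroke cluster
  (how much of the cluster is contralateral), not over the contralateral
  hemisphere; the alternative denominator is available as an option. The
  cluster-relative reading is the one that makes the quantity a property of
  the selected component.
* **Stopping at the *first* plateau is deliberate.** At large K the EM
  solution eventually fragments the stroke cluster into tight subclusters;
  a fragment can be purely ipsilateral, so its fraction drops spuriously
  toward zero. A rule that hunted the global minimum over the scan would
  chase exactly these degenerate solutions (we observed fragments of a few
  dozen voxels winning the selection that way). The first-plateau rule
  caps complexity before fragmentation sets in. Both boundary behaviors
  are defined: a sequence that is flat from the start yields the smallest
  scanned K, and a sequence that never plateaus yields the largest K with
  a warning.

### EM: initialization, regularization, and rare clusters

EM controls are conventional: full 2 × 2 covariances, a 10⁻⁶ ridge added to
covariance diagonals at every M-step, at most 500 iterations, relative
log-likelihood tolerance 10⁻⁶, k-means++-style seeded initialization. Every
fit is a pure function of (data, K, seed). For cohort-scale inputs EM runs
on a seeded subsample (default 20 000 observations); the full dataset is
always labeled exactly by one E-step under the fitted parameters, and all
member statistics (counts, raw means) refer to the full dataset.

Plain distance-based initialization has a blind spot that matters here: a
diagnostically critical cluster can be a fraction of a percent of the data
(a low-ADC imaging artifact occupying a few hundred voxels of a
several-hundred-thousand-voxel cohort). k-means++ essentially never seeds
it, and Lloyd refinement erases the rare seeds that do occur, even though
the mixture solution that models the artifact separately dominates the
merged one in likelihood. `select_model_order()` therefore runs a second
candidate at each K: a greedy-insertion fit that warm-starts from the
previous K's winner plus one new component seeded where the current model
fits worst (insertion centers are found by clustering the lowest-density
observations, so a coherent blob of poorly modeled voxels produces a
candidate even when single worst points are scattered tail noise). The
candidate that wins on log-likelihood — evaluated on the shared fitting
subsample, so the comparison is fair — becomes that K's fit. With this in
place the fraction sequence falls until the real structure (including rare
artifact clusters) is modeled and then plateaus, which is precisely the
regime the model-order rule assumes. Standalone `fit_gmm()` keeps the plain
seeded k-means++ initialization.

### Stage 2: the random forest

The classifier is trained on the mixture's binarized labels (everything
outside c\* is non-stroke, whatever its tissue type) with 100 trees, both
features candidates at every split, minimum leaf size 1, bootstrap
resampling and Gini impurity, grown single-threaded under a stored seed.
The per-voxel stroke probability is the fraction of trees voting stroke, so
probabilities lie exactly on the lattice {0, 0.01, …, 1}; label maps
binarize at 0.5 (majority vote) by default — a package decision, as
probability maps by themselves do not fix a cutoff. The feature order
(ADC first, T2W second) and the normalization recipe are serialized with
the model, because a silent feature swap or a recipe mismatch between
training and prediction is the classic failure mode of this design.

Two normalization regimes are used deliberately:

* within-species: *raw* features, because ADC is quantitative and T2W comes
  from one protocol;
* cross-scanner/species transfer: raw ADC with *per-instance* T2W z-scoring
  (`instance_t2w`), which removes any affine T2W shift exactly. The recipe
  stores the training statistics for the record, but application recomputes
  the statistics from the data being transformed — that recomputation is
  what makes the transform transferable to unseen instances.

### Baselines and evaluation

The two comparator segmentations are strict-inequality threshold rules:
stroke iff ADC < 680 (boundary voxels non-stroke), and stroke iff
T2W > 1.25 × mean contralateral T2W, the mean taken over all in-brain
contralateral voxels with no tissue exclusions. Strictness and the
contralateral-mean definition are stated so that voxel counts are
bit-reproducible. Both rules are restricted to the brain mask.

`confusion_metrics()` fixes every degenerate-case convention explicitly: a
rate with zero denominator is `NaN` and flagged in the report's `undefined`
field; the Matthews correlation coefficient with any zero factor under the
root is 0; the Dice coefficient of two empty masks is 1. The default
evaluation mask is the whole brain; ipsilateral-only and named-slice masks
(for histology-matched evaluation) are supported the same way. The median
filter defaults to a 3 × 3 × 3 majority vote with out-of-volume positions
counting as non-stroke.

## The phantom

The generator emulates the feature-space structure the framework assumes,
not brain anatomy: an ellipsoidal brain split by a midline into hemispheres,
i.i.d. Gaussian channel noise, an ellipsoidal ischemic core restricted to
the ipsilateral side, and two optional confounders — an edema rim (T2W from
the stroke distribution, ADC healthy) and a contralateral artifact blob
(ADC from the stroke distribution, T2W healthy). Default generating
distributions are healthy ADC N(800, 80), healthy T2W N(90, 15), stroke ADC
N(500, 60), stroke T2W N(130, 15), with ADC clipped at zero — centers
placed inside the empirically typical ranges (ADC mostly 500–1100 × 10⁻⁶
mm²/s with stroke below ~600; T2W mostly 50–125 a.u.), since the ranges,
not the moments, are what is empirically established. Geometry defaults are
a rat-like 64 × 64 × 24 grid at 0.25 × 0.25 × 1 mm with cohort sizes
12 training / 20 testing subjects; a human-like preset (96 × 96 × 24 at
1 × 1 × 5 mm, with a T2W scale shift) is provided. Lesion position and size
are jittered per subject; every subject is a pure function of (config,
seed), with per-subject seeds derived from the master seed so cohorts are
reproducible subject by subject.

What the phantom does **not** emulate — and hence what passing tests do not
show about real data: spatial autocorrelation and texture (optional
Gaussian smoothing exists but is off by default, as the framework is
voxel-wise), partial-volume effects at lesion boundaries, intensity
non-uniformity and bias fields, inter-subject biological variability of the
channel distributions, and registration error between channels. Results on
phantoms bound what the algorithms can do under their own assumptions; they
do not certify performance on scanner data.

## Problem sizes and runtime choices

The shipped test-suite and acceptance-script experiments use the default
cohort (12/20 subjects, ~25 000 in-brain voxels per subject, ~300 000
pooled training voxels), EM on 20 000-voxel fitting subsamples, and five
master seeds for the multi-seed recovery batteries; single-operation unit
tests use a reduced 32 × 32 × 12 phantom. These sizes were chosen so a
complete experiment runs in about a minute on one CPU while keeping the
stroke cluster (~3 % of voxels) and the artifact (~0.3 %) at realistic
rarity; the statistical behavior of every component is already stable at
this scale.

## Known limitations

* **Tree ensembles extrapolate the stroke region without bound.** Under an
  *expanding* affine T2W shift (scale > 1), a raw-recipe classifier still
  assigns shifted core voxels to stroke — the low-ADC/high-T2W leaves
  extend to infinity in T2W — so its recall stays at essentially 1.0 while
  its false-positive rate inflates. The practical consequence: recall alone
  cannot demonstrate the need for instance normalization in that direction
  of shift (under a compressing shift it collapses instead); precision and
  false-positive behavior can. Instance normalization remains the only
  variant that is correct by construction across affine shifts.
* The stroke-component score μ_T2W/μ_ADC can prefer a tiny extreme
  subcluster if the mixture has fragmented; the first-plateau model-order
  rule is the guard, and the diagnostic scan table (`fractions`, member
  counts, per-component raw means) should be inspected when results look
  odd.
* The contralateral fraction is computed pooled across the training cohort;
  per-animal fractions are available from the per-K fits for diagnostics
  but do not drive selection.
* Hemisphere labels are taken as given (the occlusion side is declared
  upstream, never inferred), and the classifier itself never sees them.
* Linear voxel indices follow R's native column-major array order
  throughout; any fixed convention round-trips exactly, and the native one
  keeps `volume[index]` valid in user code.
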