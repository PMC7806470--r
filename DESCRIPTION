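Package: strokeseg
Title: Two-Stage Unsupervised-to-Supervised Ischemic Stroke Segmentation
    from ADC/T2W MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise segmentation of acute ischemic stroke lesions from
    co-registered apparent diffusion coefficient (ADC) maps and T2-weighted
    (T2W) MRI volumes. Stage one fits Gaussian mixture models to the pooled,
    z-scored two-channel voxel features of a training cohort, selects the
    stroke component by its reduced-ADC/elevated-T2W signature, and chooses
    the model order by the contralateral stroke fraction (the contralateral
    hemisphere acting as a lesion-free negative control). Stage two trains a
    random-forest classifier on the mixture-derived binary labels and
    produces per-voxel stroke probability and label maps for unseen
    subjects, including a per-instance T2W normalization variant for
    transfer across scanners and species. The package also provides the
    classical fixed-ADC and relative-T2W thresholding baselines, a complete
    segmentation evaluation battery (confusion-matrix metrics, Dice,
    Matthews correlation, lesion volumes, joint probability maps, median
    filter post-processing), a seeded synthetic phantom generator for
    end-to-end testing, and a pipeline orchestrator with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ranger,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
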