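#' Fixed-ADC threshold baseline
#'
#' The classical acute-stroke rule: a voxel is stroke iff it is in-brain and
#' its ADC lies strictly below a fixed cutoff, 680 (in units of 1e-6 mm^2/s)
#' by default. Boundary voxels (ADC exactly at the cutoff) are non-stroke, so
#' counts are bit-reproducible.
#'
#' @param subject a [subject_dataset()].
#' @param adc_cutoff cutoff in 1e-6 mm^2/s (default 680).
#' @return binary 3-D label map on the subject grid.
#' @export
adc_threshold <- function(subject, adc_cutoff = 680) {
  stopifnot(inherits(subject, "subject_dataset"), adc_cutoff > 0)
  array(as.numeric(subject$brain_mask == 1 & subject$adc < adc_cutoff),
        dim(subject$adc))
}

#' Relative-T2W threshold baseline
#'
#' A voxel is stroke iff it is in-brain and its T2W intensity strictly
#' exceeds `t2w_factor` times the mean T2W of the contralateral hemisphere
#' (125% by default). Using the contralateral mean as the reference makes the
#' rule invariant to any multiplicative rescaling of the whole T2W image. The
#' contralateral mean is taken over all in-brain contralateral voxels.
#'
#' @param subject a [subject_dataset()].
#' @param t2w_factor multiple of the contralateral mean (default 1.25).
#' @return binary 3-D label map on the subject grid.
#' @export
t2w_threshold <- function(subject, t2w_factor = 1.25) {
  stopifnot(inherits(subject, "subject_dataset"), t2w_factor > 0)
  contra <- subject$hemisphere_mask == 2
  if (!any(contra)) {
    stop("undefined-threshold error: subject has no contralateral in-brain voxels")
  }
  cutoff <- t2w_factor * mean(subject$t2w[contra])
  array(as.numeric(subject$brain_mask == 1 & subject$t2w > cutoff),
        dim(subject$t2w))
}
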