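#' Confusion-matrix metrics for one (prediction, reference) pair
#'
#' Counts TP/FP/FN/TN over the evaluation mask and derives the full metric
#' battery: accuracy, sensitivity, specificity, positive and negative
#' predictive values, false discovery rate, false positive rate, the Dice
#' similarity coefficient DSC = 2TP / (2TP + FP + FN) and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' Conventions for degenerate cases, so reports are bit-reproducible: a rate
#' with zero denominator is `NaN` and its name is listed in `undefined`; MCC
#' with any zero factor under the root is 0; DSC of two empty masks is 1.
#'
#' @param pred,ref binary 3-D arrays (or logical) on a common grid.
#' @param eval_mask binary array restricting the evaluation (e.g. whole brain,
#'   ipsilateral hemisphere, or a histology-matched slice set); voxels outside
#'   it are ignored entirely.
#' @param mask_name descriptor stored in the report (default
#'   `"whole_brain"`).
#' @return object of class `metrics_report` (also a one-row list): counts,
#'   all metrics, `mask_name`, `undefined`.
#' @export
confusion_metrics <- function(pred, ref, eval_mask, mask_name = "whole_brain") {
  if (!identical(dim(pred), dim(ref)) || !identical(dim(pred), dim(eval_mask))) {
    stop("geometry error: pred, ref and eval_mask must share one grid")
  }
  m <- eval_mask > 0
  if (!any(m)) stop("empty evaluation mask")
  p <- pred[m] > 0; r <- ref[m] > 0
  TP <- sum(p & r); FP <- sum(p & !r); FN <- sum(!p & r); TN <- sum(!p & !r)
  rate <- function(num, den) if (den == 0) NaN else num / den
  acc <- rate(TP + TN, TP + FP + FN + TN)
  sens <- rate(TP, TP + FN)
  spec <- rate(TN, TN + FP)
  ppv <- rate(TP, TP + FP)
  npv <- rate(TN, TN + FN)
  fdr <- if (TP + FP == 0) NaN else 1 - ppv
  fpr <- if (TN + FP == 0) NaN else 1 - spec
  dsc <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
  fac <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(fac == 0)) 0 else
    (TP * TN - FP * FN) / sqrt(prod(fac))
  out <- list(TP = TP, FP = FP, FN = FN, TN = TN,
              accuracy = acc, sensitivity = sens, specificity = spec,
              PPV = ppv, NPV = npv, FDR = fdr, FPR = fpr,
              DSC = dsc, MCC = mcc, mask_name = mask_name,
              undefined = names(which(is.nan(c(
                accuracy = acc, sensitivity = sens, specificity = spec,
                PPV = ppv, NPV = npv, FDR = fdr, FPR = fpr)))))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report [", x$mask_name, "]: TP=", x$TP, " FP=", x$FP,
      " FN=", x$FN, " TN=", x$TN, "\n", sep = "")
  v <- unlist(x[c("accuracy", "sensitivity", "specificity", "PPV", "NPV",
                  "FDR", "FPR", "DSC", "MCC")])
  print(round(v, 4))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Turn metrics reports into a data frame
#'
#' @param reports a `metrics_report` or list of them (optionally named).
#' @return data.frame, one row per report.
#' @export
metrics_table <- function(reports) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  cols <- c("TP", "FP", "FN", "TN", "accuracy", "sensitivity", "specificity",
            "PPV", "NPV", "FDR", "FPR", "DSC", "MCC", "mask_name")
  out <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(r[cols], stringsAsFactors = FALSE)))
  if (!is.null(names(reports))) out <- cbind(id = names(reports), out)
  rownames(out) <- NULL
  out
}

#' Lesion volume of a binary map
#'
#' @param map binary 3-D array.
#' @param voxel_dims voxel edge lengths in mm.
#' @param restrict_to optional binary array (e.g. the ipsilateral hemisphere)
#'   intersected with the map before counting.
#' @return volume in mm^3.
#' @export
lesion_volume <- function(map, voxel_dims, restrict_to = NULL) {
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  m <- map > 0
  if (!is.null(restrict_to)) {
    if (!identical(dim(restrict_to), dim(map))) {
      stop("geometry error: restriction mask not on the map grid")
    }
    m <- m & restrict_to > 0
  }
  sum(m) * prod(voxel_dims)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation of two equal-length vectors (e.g. per-subject
#' predicted lesion volumes against reference volumes or histology areas),
#' with the two-sided p-value from the t transform on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate error: constant input vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Joint probability map of a set of binary segmentations
#'
#' Per-voxel fraction of subjects whose segmentation includes the voxel, on a
#' common (e.g. template) grid; the superposition used to visualize the
#' average lesion across a cohort.
#'
#' @param maps list of binary 3-D arrays on one grid.
#' @return 3-D field with values on the lattice 0, 1/n, ..., 1.
#' @export
joint_probability_map <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  d <- dim(maps[[1]])
  acc <- array(0, d)
  for (m in maps) {
    if (!identical(dim(m), d)) stop("geometry error: maps are not on one grid")
    acc <- acc + (m > 0)
  }
  acc / length(maps)
}

#' Count scattered false-positive stroke voxels in a lesion-free subject
#'
#' For subjects the reference declares lesion-free (e.g. suspected transient
#' ischemic attack), every segmented voxel is a false positive; this is their
#' count.
#'
#' @param map binary 3-D array.
#' @return integer count.
#' @export
scattered_false_positive_count <- function(map) {
  sum(map > 0)
}
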