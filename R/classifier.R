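#' Collapse mixture labels to binary stroke / non-stroke labels
#'
#' Voxels in the selected stroke component become `"stroke"`; voxels of every
#' other component become `"non-stroke"` irrespective of their tissue
#' characteristics, turning the multi-class clustering into the two-class
#' supervised problem the classifier is trained on.
#'
#' @param fit a [fit_gmm()] with `stroke_component` set.
#' @return factor with levels `c("non-stroke", "stroke")`, one per
#'   observation.
#' @export
binarize_gmm_labels <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (is.na(fit$stroke_component)) {
    stop("stroke_component not set; run select_stroke_component() first")
  }
  factor(ifelse(fit$labels == fit$stroke_component, "stroke", "non-stroke"),
         levels = c("non-stroke", "stroke"))
}

#' Train the voxel-wise stroke random forest
#'
#' 100 trees, both features sampled at every split, minimum of one
#' observation per leaf, bootstrap resampling and Gini impurity (library
#' defaults otherwise), grown single-threaded under the given seed. The
#' normalization recipe the features were prepared under is stored with the
#' model and re-applied identically at prediction time, as is the feature
#' order (ADC first, T2W second).
#'
#' @param features feature table of the training cohort (raw values; the
#'   recipe is applied internally).
#' @param labels binary factor from [binarize_gmm_labels()] (or any
#'   two-level factor with a `"stroke"` level), one per row.
#' @param recipe a [make_recipe()]; `raw` for the within-species arm,
#'   `instance_t2w` for the cross-scanner transfer arm.
#' @param seed integer seed.
#' @param n_trees,min_leaf forest size and leaf size (defaults 100 and 1).
#' @return object of class `stroke_classifier`.
#' @export
train_classifier <- function(features, labels, recipe, seed,
                             n_trees = 100, min_leaf = 1) {
  stopifnot(inherits(recipe, "normalization_recipe"),
            nrow(features) == length(labels))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("training error: both classes must be present in the labels")
  }
  prepared <- apply_recipe(recipe, features)
  x <- data.frame(adc = prepared$adc, t2w = prepared$t2w)
  if (any(!is.finite(x$adc)) || any(!is.finite(x$t2w))) {
    stop("validation error: non-finite feature values after normalization")
  }
  forest <- ranger::ranger(x = x, y = droplevels(labels),
                           num.trees = n_trees, mtry = 2,
                           min.node.size = min_leaf,
                           replace = TRUE, splitrule = "gini",
                           seed = seed, num.threads = 1)
  structure(list(forest = forest, recipe = recipe, seed = seed,
                 n_trees = n_trees, min_leaf = min_leaf,
                 feature_order = c("adc", "t2w"),
                 stroke_level = which(forest$forest$levels == "stroke"),
                 version = as.character(utils::packageVersion("strokeseg"))),
            class = "stroke_classifier")
}

#' @export
print.stroke_classifier <- function(x, ...) {
  cat("stroke_classifier:", x$n_trees, "trees, min leaf", x$min_leaf,
      "| recipe:", x$recipe$mode, "| seed:", x$seed, "\n")
  invisible(x)
}

# vote-fraction stroke probabilities for a prepared feature data.frame
forest_votes <- function(classifier, x) {
  pred <- stats::predict(classifier$forest, data = x, predict.all = TRUE,
                         num.threads = 1)
  rowMeans(pred$predictions == classifier$stroke_level)
}

#' Predict a per-voxel stroke probability map for one subject
#'
#' Applies the classifier's stored normalization recipe to the subject's
#' features, scores every in-brain voxel by the fraction of trees voting
#' stroke, and maps probabilities back to the subject grid. The probability
#' map is binarized at `threshold` to a label map.
#'
#' @param classifier a [train_classifier()] model.
#' @param subject a [subject_dataset()].
#' @param threshold binarization cutoff on the probability (default 0.5,
#'   i.e. majority vote).
#' @return object of class `probability_map`: `probability` (3-D field in
#'   \[0,1\], 0 outside the brain), `labels` (binary 3-D field,
#'   probability >= threshold within the brain), `threshold`, `subject_id`.
#' @export
predict_subject <- function(classifier, subject, threshold = 0.5) {
  stopifnot(inherits(classifier, "stroke_classifier"),
            inherits(subject, "subject_dataset"),
            threshold >= 0, threshold <= 1)
  tab <- to_feature_table(subject)
  prepared <- apply_recipe(classifier$recipe, tab)
  x <- data.frame(adc = prepared$adc, t2w = prepared$t2w)
  p <- forest_votes(classifier, x)
  prob <- map_back(tab$voxel_index, p, subject)
  lab <- map_back(tab$voxel_index, as.numeric(p >= threshold), subject)
  structure(list(probability = prob, labels = lab, threshold = threshold,
                 subject_id = subject$subject_id),
            class = "probability_map")
}

#' Predict on a scanner-shifted subject with per-instance T2W normalization
#'
#' The cross-scanner / cross-species arm: requires a classifier trained under
#' the `instance_t2w` recipe, whose per-subject T2W z-scoring removes any
#' affine intensity shift between scanners; ADC, being quantitative, passes
#' through raw.
#'
#' @inheritParams predict_subject
#' @return a `probability_map` (see [predict_subject()]).
#' @export
transfer_predict <- function(classifier, subject, threshold = 0.5) {
  stopifnot(inherits(classifier, "stroke_classifier"))
  if (classifier$recipe$mode != "instance_t2w") {
    stop("transfer prediction requires a classifier trained under the ",
         "'instance_t2w' recipe, not '", classifier$recipe$mode, "'")
  }
  predict_subject(classifier, subject, threshold)
}

#' Save / load a stroke classifier
#'
#' The serialized file carries the forest, the normalization recipe, the
#' training seed and the feature-order contract, so a loaded model predicts
#' identically to the one trained.
#'
#' @param classifier a `stroke_classifier`.
#' @param path file path (`.rds`).
#' @return `save_classifier` the path invisibly; `load_classifier` the model.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "stroke_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "stroke_classifier")) stop("not a stroke_classifier file")
  obj
}
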