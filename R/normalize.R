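#' Build a normalization recipe for the two-channel features
#'
#' Three modes are supported, matching the three ways features enter the
#' framework:
#' \describe{
#'   \item{`population_zscore`}{both channels z-scored with statistics pooled
#'     over all subjects' in-brain voxels; used before mixture-model
#'     clustering, where distance-based fitting is sensitive to the scale
#'     difference between ADC and T2W.}
#'   \item{`instance_t2w`}{T2W z-scored per subject with that subject's own
#'     in-brain mean and standard deviation, ADC left raw; used for transfer
#'     to data acquired on another scanner or field strength, where T2W
#'     (non-quantitative) is not comparable across instances but ADC
#'     (quantitative) is.}
#'   \item{`raw`}{identity; the classifier of the within-species arm is
#'     trained on un-normalized features.}
#' }
#'
#' @param mode one of `"population_zscore"`, `"instance_t2w"`, `"raw"`.
#' @param features a feature table from [to_feature_table()]; required for the
#'   normalizing modes (statistics are computed from it and stored).
#' @return an object of class `normalization_recipe` holding the mode and the
#'   statistics used. For `instance_t2w` the recipe stores the training
#'   subjects' per-instance statistics for the record, but application always
#'   recomputes the statistics from the data being transformed — that is what
#'   makes the transform transferable to unseen instances.
#' @export
make_recipe <- function(mode = c("population_zscore", "instance_t2w", "raw"),
                        features = NULL) {
  mode <- match.arg(mode)
  stats_out <- NULL
  if (mode == "population_zscore") {
    stopifnot(!is.null(features), nrow(features) >= 2)
    m <- c(adc = mean(features$adc), t2w = mean(features$t2w))
    s <- c(adc = stats::sd(features$adc), t2w = stats::sd(features$t2w))
    if (any(!is.finite(c(m, s))) || any(s <= 0)) {
      stop("degenerate-input error: zero or non-finite variance in a channel ",
           "to be normalized")
    }
    stats_out <- list(mean = m, sd = s)
  } else if (mode == "instance_t2w") {
    stopifnot(!is.null(features))
    per <- instance_t2w_stats(features)
    stats_out <- list(per_subject = per)
  }
  structure(list(mode = mode, stats = stats_out), class = "normalization_recipe")
}

instance_t2w_stats <- function(features) {
  ids <- unique(features$subject_id)
  per <- data.frame(subject_id = ids,
                    t2w_mean = NA_real_, t2w_sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    v <- features$t2w[features$subject_id == ids[i]]
    if (length(v) < 2) stop("degenerate-input error: subject '", ids[i],
                            "' has fewer than 2 in-brain voxels")
    per$t2w_mean[i] <- mean(v)
    per$t2w_sd[i] <- stats::sd(v)
    if (!is.finite(per$t2w_sd[i]) || per$t2w_sd[i] <= 0) {
      stop("degenerate-input error: constant T2W channel in subject '", ids[i], "'")
    }
  }
  per
}

#' Apply a normalization recipe to a feature table
#'
#' @param recipe a [make_recipe()] result.
#' @param features a feature table (any cohort; `instance_t2w` recomputes
#'   per-subject statistics from these data).
#' @return the transformed feature table with its `provenance` attribute
#'   updated per channel.
#' @export
apply_recipe <- function(recipe, features) {
  stopifnot(inherits(recipe, "normalization_recipe"))
  prov <- provenance(features)
  if (recipe$mode == "population_zscore") {
    features$adc <- (features$adc - recipe$stats$mean["adc"]) / recipe$stats$sd["adc"]
    features$t2w <- (features$t2w - recipe$stats$mean["t2w"]) / recipe$stats$sd["t2w"]
    prov[] <- "population_zscore"
  } else if (recipe$mode == "instance_t2w") {
    per <- instance_t2w_stats(features)
    i <- match(features$subject_id, per$subject_id)
    features$t2w <- (features$t2w - per$t2w_mean[i]) / per$t2w_sd[i]
    prov["t2w"] <- "instance_zscore"
  }
  attr(features, "provenance") <- prov
  features
}
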