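#' Configuration for the full segmentation experiment
#'
#' Bundles per-stage settings: the phantom generator, the model-order scan,
#' the forest, the threshold baselines, binarization and post-processing, and
#' the master seed. Every randomized stage derives its own seed from the
#' master seed and the stage name, so stages are reproducible independently.
#'
#' @param phantom a [phantom_config()].
#' @param K_range model orders scanned by the contralateral-fraction rule.
#' @param eps plateau tolerance.
#' @param gmm_fit_subsample EM fitting subsample size (full-cohort labeling is
#'   always exact; see [fit_gmm()]).
#' @param n_trees,min_leaf forest parameters.
#' @param adc_cutoff,t2w_factor baseline thresholds.
#' @param binarize_threshold probability cutoff for label maps.
#' @param median_filter,median_kernel optional label-map post-processing.
#' @param transfer logical: also run the cross-scanner arm (instance-T2W
#'   classifier on test subjects shifted by the phantom's `t2w_scale_shift`).
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            K_range = 2:8, eps = 0.01,
                            gmm_fit_subsample = 20000,
                            n_trees = 100, min_leaf = 1,
                            adc_cutoff = 680, t2w_factor = 1.25,
                            binarize_threshold = 0.5,
                            median_filter = FALSE, median_kernel = 3,
                            transfer = FALSE,
                            seed = 20240101) {
  stopifnot(inherits(phantom, "phantom_config"))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the `phantom` map holds
#' [phantom_config()] arguments. `K_range` may be given as `[min, max]`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, as.list(raw$phantom %||% list()))
  rest <- raw[setdiff(names(raw), "phantom")]
  if (!is.null(rest$K_range) && length(rest$K_range) == 2) {
    rest$K_range <- seq(rest$K_range[1], rest$K_range[2])
  }
  do.call(pipeline_config, c(list(phantom = ph), rest))
}

#' Run the full experiment: phantoms to evaluation report
#'
#' Stages, in order: `simulate` (seeded training/testing cohorts), `label`
#' (population z-scoring, model-order scan, stroke-component selection,
#' binary label generation), `train` (random forest on the raw training
#' features; plus an instance-T2W forest when the transfer arm is on),
#' `predict` (probability and label maps for every test subject; transfer
#' predictions on scanner-shifted copies when enabled), `threshold` (both
#' baselines), `evaluate` (per-subject metric battery against the planted
#' core, lesion volumes and ratios to the estimated ground truth, volume
#' correlations, joint probability map).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, all artifacts
#'   (cohort volumes, scan JSON, model files, maps, CSV reports, run
#'   manifest) are written there.
#' @param until last stage to run, one of `"simulate"`, `"label"`, `"train"`,
#'   `"predict"`, `"threshold"`, `"evaluate"` (default: everything).
#' @param quiet suppress progress messages.
#' @return a list of class `pipeline_result` with (depending on `until`)
#'   `cohort`, `scan`, `classifier`, `classifier_transfer`, `predictions`,
#'   `transfer_predictions`, `baselines`, `metrics`, `volumes`,
#'   `correlations`, `joint_map`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         until = c("evaluate", "simulate", "label", "train",
                                   "predict", "threshold"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  until <- match.arg(until)
  stages <- c("simulate", "label", "train", "predict", "threshold", "evaluate")
  last <- match(until, stages)
  say <- function(...) if (!quiet) message("[strokeseg] ", ...)

  # validation before any compute
  if (config$phantom$n_test < 1) {
    stop("validation error: testing cohort size must be >= 1")
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- config$seed
  res <- list(config = config,
              manifest = list(package = "strokeseg",
                              version = as.character(utils::packageVersion("strokeseg")),
                              master_seed = master,
                              stage_seeds = list(), files = character(0)))
  keep <- function(path) {
    if (!is.null(path)) res$manifest$files <<- c(res$manifest$files, path)
  }

  ## simulate
  seed_sim <- derive_seed(master, "simulate")
  res$manifest$stage_seeds$simulate <- seed_sim
  say("simulate: ", config$phantom$n_train, " training + ",
      config$phantom$n_test, " testing subjects")
  res$cohort <- generate_cohort(config$phantom, seed_sim)
  if (!is.null(out_dir) && last == 1) {
    for (s in c(res$cohort$training, res$cohort$testing)) {
      keep(unname(write_subject(s, file.path(out_dir, "cohort"))))
    }
    keep(write_cohort_manifest(res$cohort, file.path(out_dir, "cohort_manifest.csv")))
  }
  if (last == 1) return(finish_pipeline(res, out_dir))

  ## label
  seed_lab <- derive_seed(master, "label")
  res$manifest$stage_seeds$label <- seed_lab
  train_tab <- to_feature_table(res$cohort$training)
  pop_recipe <- make_recipe("population_zscore", train_tab)
  norm_tab <- apply_recipe(pop_recipe, train_tab)
  say("label: model-order scan over K = ", paste(range(config$K_range), collapse = ".."))
  res$scan <- select_model_order(norm_tab, K_range = config$K_range,
                                 eps = config$eps, seed = seed_lab,
                                 raw = train_tab,
                                 fit_subsample = config$gmm_fit_subsample)
  res$manifest$chosen_k <- res$scan$chosen_k
  say("label: chosen K* = ", res$scan$chosen_k, ", stroke component ",
      res$scan$chosen_fit$stroke_component)
  labels_bin <- binarize_gmm_labels(res$scan$chosen_fit)
  if (!is.null(out_dir)) {
    keep(write_scan_json(res$scan, file.path(out_dir, "model_order_scan.json")))
    lab_dir <- file.path(out_dir, "gmm_labels")
    dir.create(lab_dir, showWarnings = FALSE)
    for (s in res$cohort$training) {
      rows <- train_tab$subject_id == s$subject_id
      keep(write_volume(map_back(train_tab$voxel_index[rows],
                                 res$scan$chosen_fit$labels[rows], s),
                        file.path(lab_dir, paste0(s$subject_id, "_gmm_labels.nii.gz")),
                        s))
    }
  }
  if (last == 2) return(finish_pipeline(res, out_dir))

  ## train
  seed_tr <- derive_seed(master, "train")
  res$manifest$stage_seeds$train <- seed_tr
  say("train: random forest on ", nrow(train_tab), " voxels (",
      sum(labels_bin == "stroke"), " stroke)")
  res$classifier <- train_classifier(train_tab, labels_bin, make_recipe("raw"),
                                     seed = seed_tr, n_trees = config$n_trees,
                                     min_leaf = config$min_leaf)
  if (config$transfer) {
    res$classifier_transfer <- train_classifier(
      train_tab, labels_bin, make_recipe("instance_t2w", train_tab),
      seed = derive_seed(master, "train-transfer"),
      n_trees = config$n_trees, min_leaf = config$min_leaf)
  }
  if (!is.null(out_dir)) {
    keep(save_classifier(res$classifier, file.path(out_dir, "classifier.rds")))
    if (config$transfer) {
      keep(save_classifier(res$classifier_transfer,
                           file.path(out_dir, "classifier_transfer.rds")))
    }
  }
  if (last == 3) return(finish_pipeline(res, out_dir))

  ## predict
  say("predict: ", length(res$cohort$testing), " test subjects")
  res$predictions <- lapply(res$cohort$testing, function(s) {
    pm <- predict_subject(res$classifier, s, config$binarize_threshold)
    if (config$median_filter) {
      pm$labels <- median_filter_labels(pm$labels, config$median_kernel)
    }
    pm
  })
  names(res$predictions) <- vapply(res$cohort$testing, `[[`, "", "subject_id")
  if (config$transfer) {
    sc <- config$phantom$t2w_scale_shift
    res$transfer_predictions <- lapply(res$cohort$testing, function(s) {
      shifted <- apply_scanner_shift(s, sc[1], sc[2])
      pm <- transfer_predict(res$classifier_transfer, shifted,
                             config$binarize_threshold)
      if (config$median_filter) {
        pm$labels <- median_filter_labels(pm$labels, config$median_kernel)
      }
      pm
    })
    names(res$transfer_predictions) <- names(res$predictions)
  }
  if (!is.null(out_dir)) {
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (i in seq_along(res$predictions)) {
      s <- res$cohort$testing[[i]]; pm <- res$predictions[[i]]
      keep(write_volume(pm$probability,
                        file.path(map_dir, paste0(s$subject_id, "_ml_prob.nii.gz")), s))
      keep(write_volume(pm$labels,
                        file.path(map_dir, paste0(s$subject_id, "_ml_labels.nii.gz")), s))
    }
  }
  if (last == 4) return(finish_pipeline(res, out_dir))

  ## threshold baselines
  say("threshold: ADC < ", config$adc_cutoff, ", T2W > ",
      config$t2w_factor, " x contralateral mean")
  res$baselines <- lapply(res$cohort$testing, function(s) {
    list(ADCth = adc_threshold(s, config$adc_cutoff),
         T2Wth = t2w_threshold(s, config$t2w_factor))
  })
  names(res$baselines) <- names(res$predictions)
  if (!is.null(out_dir)) {
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (i in seq_along(res$baselines)) {
      s <- res$cohort$testing[[i]]
      keep(write_volume(res$baselines[[i]]$ADCth,
                        file.path(map_dir, paste0(s$subject_id, "_adcth.nii.gz")), s))
      keep(write_volume(res$baselines[[i]]$T2Wth,
                        file.path(map_dir, paste0(s$subject_id, "_t2wth.nii.gz")), s))
    }
  }
  if (last == 5) return(finish_pipeline(res, out_dir))

  ## evaluate
  say("evaluate: metric battery against the planted core")
  ev <- evaluate_cohort(res$cohort$testing, res$predictions, res$baselines,
                        transfer_predictions = res$transfer_predictions)
  res$metrics <- ev$metrics
  res$volumes <- ev$volumes
  res$correlations <- ev$correlations
  res$joint_map <- joint_probability_map(lapply(res$predictions, `[[`, "labels"))
  if (!is.null(out_dir)) {
    mp <- file.path(out_dir, "metrics.csv")
    utils::write.csv(res$metrics, mp, row.names = FALSE); keep(mp)
    vp <- file.path(out_dir, "volumes.csv")
    utils::write.csv(res$volumes, vp, row.names = FALSE); keep(vp)
    keep(write_volume(res$joint_map, file.path(out_dir, "joint_probability_ml.nii.gz"),
                      res$cohort$testing[[1]]))
  }
  finish_pipeline(res, out_dir)
}

# per-subject, per-method metric battery + volume records + correlations
evaluate_cohort <- function(testing, predictions, baselines,
                            transfer_predictions = NULL, reference = "core") {
  method_maps <- function(i) {
    m <- list(ML = predictions[[i]]$labels,
              ADCth = baselines[[i]]$ADCth,
              T2Wth = baselines[[i]]$T2Wth)
    if (!is.null(transfer_predictions)) {
      m$ML_transfer <- transfer_predictions[[i]]$labels
    }
    m
  }
  met_rows <- list(); vol_rows <- list()
  for (i in seq_along(testing)) {
    s <- testing[[i]]
    ref <- s$reference_masks[[reference]]
    if (is.null(ref)) stop("subject '", s$subject_id, "' lacks reference mask '",
                           reference, "'")
    egt <- s$reference_masks[["EGT"]] %||% ref
    ipsi <- s$hemisphere_mask == 1
    egt_vol <- lesion_volume(egt, s$voxel_dims)
    egt_vol_ipsi <- lesion_volume(egt, s$voxel_dims, ipsi)
    mm <- method_maps(i)
    for (meth in names(mm)) {
      map <- mm[[meth]]
      rep <- confusion_metrics(map, ref, s$brain_mask)
      met_rows[[length(met_rows) + 1]] <-
        cbind(subject_id = s$subject_id, method = meth, metrics_table(rep))
      vol <- lesion_volume(map, s$voxel_dims)
      vol_ipsi <- lesion_volume(map, s$voxel_dims, ipsi)
      vol_rows[[length(vol_rows) + 1]] <- data.frame(
        subject_id = s$subject_id, method = meth,
        volume_mm3 = vol, volume_ipsi_mm3 = vol_ipsi,
        egt_volume_mm3 = egt_vol,
        ratio_to_egt = if (egt_vol > 0) vol / egt_vol else NA_real_,
        ratio_to_egt_ipsi = if (egt_vol_ipsi > 0) vol_ipsi / egt_vol_ipsi else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, met_rows)
  volumes <- do.call(rbind, vol_rows)
  correlations <- list()
  egt_per_subject <- volumes$egt_volume_mm3[volumes$method == "ML"]
  for (meth in unique(volumes$method)) {
    v <- volumes$volume_mm3[volumes$method == meth]
    correlations[[meth]] <- tryCatch(pearson_correlation(v, egt_per_subject),
                                     error = function(e) list(r = NA_real_,
                                                              p = NA_real_,
                                                              n = length(v)))
  }
  list(metrics = metrics, volumes = volumes, correlations = correlations)
}

write_cohort_manifest <- function(cohort, path) {
  rows <- lapply(c(training = "training", testing = "testing"), function(role) {
    do.call(rbind, lapply(cohort[[role]], function(s) data.frame(
      subject_id = s$subject_id, role = role,
      n_brain_voxels = sum(s$brain_mask),
      core_voxels = sum(s$reference_masks$core %||% 0),
      stringsAsFactors = FALSE)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  path
}

finish_pipeline <- function(res, out_dir) {
  if (!is.null(out_dir)) {
    files <- unlist(res$manifest$files)
    res$manifest$files <- data.frame(
      path = files,
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE)
    mpath <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(res$manifest, mpath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  class(res) <- "pipeline_result"
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: ", length(x$cohort$training), " train / ",
      length(x$cohort$testing), " test subjects", sep = "")
  if (!is.null(x$scan)) cat(", K* = ", x$scan$chosen_k, sep = "")
  cat("\n")
  if (!is.null(x$metrics)) {
    agg <- stats::aggregate(cbind(DSC, MCC, FPR) ~ method, data = x$metrics,
                            FUN = stats::median)
    cat("median per-subject metrics vs planted core:\n")
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
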