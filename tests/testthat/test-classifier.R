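# shared small training setting: GMM-labeled cohort without confounders
.coh <- generate_cohort(small_config(), seed = 31)
train_tab <- to_feature_table(.coh$training)
.norm <- apply_recipe(make_recipe("population_zscore", train_tab), train_tab)
train_fit <- fit_gmm(.norm, 2, seed = 1, raw = train_tab, fit_subsample = 5000)
train_fit$stroke_component <- select_stroke_component(train_fit)
train_labels <- binarize_gmm_labels(train_fit)
probe_subject <- .coh$testing[[1]]

test_that("GMM labels collapse to a binary stroke partition", {
  expect_identical(levels(train_labels), c("non-stroke", "stroke"))
  expect_equal(sum(train_labels == "stroke"),
               train_fit$counts[train_fit$stroke_component])
  expect_length(train_labels, nrow(train_tab))

  k1 <- fake_gmm_fit(mu_adc = 500, mu_t2w = 130, labels = rep(1L, 12))
  k1$stroke_component <- 1L
  expect_true(all(binarize_gmm_labels(k1) == "stroke"))
  unset <- train_fit; unset$stroke_component <- NA_integer_
  expect_error(binarize_gmm_labels(unset), "stroke_component")
})

test_that("training is deterministic, self-consistent, and validates input", {
  clf <- train_classifier(train_tab, train_labels, make_recipe("raw"), seed = 2)
  # self-fit agreement with min leaf 1
  pm <- forestless <- NULL
  votes <- strokeseg:::forest_votes(clf, data.frame(adc = train_tab$adc,
                                                   t2w = train_tab$t2w))
  agree <- mean((votes >= 0.5) == (train_labels == "stroke"))
  expect_gte(agree, 0.99)

  clf2 <- train_classifier(train_tab, train_labels, make_recipe("raw"), seed = 2)
  p1 <- predict_subject(clf, probe_subject)
  p2 <- predict_subject(clf2, probe_subject)
  expect_identical(p1$probability, p2$probability)

  expect_error(train_classifier(train_tab,
                                factor(rep("non-stroke", nrow(train_tab)),
                                       levels = c("non-stroke", "stroke")),
                                make_recipe("raw"), seed = 1),
               "training error")
  bad <- train_tab; bad$adc[1] <- NaN
  expect_error(train_classifier(bad, train_labels, make_recipe("raw"), seed = 1),
               "validation error")
})

test_that("probability maps live on the vote lattice and respect the mask", {
  clf <- train_classifier(train_tab, train_labels, make_recipe("raw"), seed = 3)
  pm <- predict_subject(clf, probe_subject, threshold = 0.5)
  expect_true(all(pm$probability >= 0 & pm$probability <= 1))
  expect_true(all(pm$probability[probe_subject$brain_mask == 0] == 0))
  inb <- probe_subject$brain_mask == 1
  # votes out of 100 trees: probabilities on the lattice {0, 0.01, ..., 1}
  expect_true(all(abs(pm$probability[inb] * 100 -
                      round(pm$probability[inb] * 100)) < 1e-9))
  expect_identical(pm$labels[inb], as.numeric(pm$probability[inb] >= 0.5))

  # voxel-wise purity: equal features receive equal probabilities
  s <- probe_subject
  idx <- which(inb)[1:2]
  s$adc[idx] <- 500; s$t2w[idx] <- 130
  pm2 <- predict_subject(clf, s)
  expect_identical(pm2$probability[idx[1]], pm2$probability[idx[2]])
  expect_gt(pm2$probability[idx[1]], 0.5)  # stroke-distribution center
})

test_that("a low-ADC artifact with normal T2W is rejected by a confounder-trained model", {
  # training labels that carry no stroke-labeled artifact voxels: the
  # artifact and edema compartments are explicit non-stroke mass
  cfg <- small_config(include_edema = TRUE, include_artifact = TRUE)
  coh <- generate_cohort(cfg, seed = 33)
  tab <- to_feature_table(coh$training)
  core_rows <- unlist(lapply(coh$training, function(s)
    s$reference_masks$core[s$brain_mask == 1] == 1))
  labels <- factor(ifelse(core_rows, "stroke", "non-stroke"),
                   levels = c("non-stroke", "stroke"))
  clf <- train_classifier(tab, labels, make_recipe("raw"), seed = 4)
  s <- coh$testing[[1]]
  inb <- which(s$brain_mask == 1)
  s$adc[inb[1]] <- 500; s$t2w[inb[1]] <- 130   # ischemic signature
  s$adc[inb[2]] <- 500; s$t2w[inb[2]] <- 90    # artifact signature
  pm <- predict_subject(clf, s)
  expect_gt(pm$probability[inb[1]], 0.5)
  expect_lt(pm$probability[inb[2]], 0.5)
})

test_that("instance-normalized transfer survives an affine scanner shift", {
  clf_inst <- train_classifier(train_tab, train_labels,
                               make_recipe("instance_t2w", train_tab), seed = 5)
  clf_raw <- train_classifier(train_tab, train_labels, make_recipe("raw"),
                              seed = 5)
  shifted <- apply_scanner_shift(probe_subject, 2, 10)
  pm <- transfer_predict(clf_inst, shifted)
  core <- probe_subject$reference_masks$core == 1
  expect_gte(sum(pm$labels[core]) / sum(core), 0.9)
  expect_error(transfer_predict(clf_raw, shifted), "instance_t2w")

  # without any shift, instance and raw recipes agree almost everywhere
  pm_id <- transfer_predict(clf_inst, probe_subject)
  pm_raw <- predict_subject(clf_raw, probe_subject)
  inb <- probe_subject$brain_mask == 1
  expect_gte(mean(pm_id$labels[inb] == pm_raw$labels[inb]), 0.95)
})

test_that("serialized classifiers predict identically after reload", {
  clf <- train_classifier(train_tab, train_labels, make_recipe("raw"), seed = 6)
  path <- tempfile(fileext = ".rds")
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  expect_identical(predict_subject(clf2, probe_subject)$probability,
                   predict_subject(clf, probe_subject)$probability)
  expect_identical(clf2$feature_order, c("adc", "t2w"))
})
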