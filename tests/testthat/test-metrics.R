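test_that("worked toy confusion matrix matches hand and oracle computation", {
  # 10-voxel evaluation mask: TP=3, FP=1, FN=1, TN=5
  grid <- c(10, 1, 1)
  evalm <- array(1, grid)
  ref <- array(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), grid)
  pred <- array(c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0), grid)
  rep <- confusion_metrics(pred, ref, evalm)
  expect_equal(rep$TP, 3); expect_equal(rep$FP, 1)
  expect_equal(rep$FN, 1); expect_equal(rep$TN, 5)
  expect_equal(rep$accuracy, 0.8)
  expect_equal(rep$DSC, 0.75)
  expect_equal(rep$MCC, 14 / 24)
  expect_equal(rep$sensitivity, 0.75)
  expect_equal(rep$specificity, 5 / 6)
  oracle <- naive_confusion(pred, ref, evalm)
  for (nm in names(oracle)) expect_equal(rep[[nm]], oracle[[nm]], label = nm)
})

test_that("metrics agree exactly with naive enumeration on random masks", {
  set.seed(17)
  for (trial in 1:25) {
    grid <- c(8, 8, 4)
    evalm <- array(rbinom(prod(grid), 1, 0.8), grid)
    ref <- array(rbinom(prod(grid), 1, 0.3), grid) * evalm
    pred <- array(rbinom(prod(grid), 1, 0.3), grid) * evalm
    rep <- confusion_metrics(pred, ref, evalm)
    oracle <- naive_confusion(pred, ref, evalm)
    for (nm in names(oracle)) expect_identical(rep[[nm]], oracle[[nm]])
  }
})

test_that("degenerate conventions are explicit and flagged", {
  grid <- c(4, 4, 2)
  evalm <- array(1, grid)
  zero <- array(0, grid)
  ref <- zero; ref[1:2, 1, 1] <- 1

  perfect <- confusion_metrics(ref, ref, evalm)
  expect_equal(perfect$DSC, 1); expect_equal(perfect$MCC, 1)
  expect_equal(perfect$FPR, 0)

  miss <- confusion_metrics(zero, ref, evalm)
  expect_equal(miss$DSC, 0); expect_equal(miss$sensitivity, 0)
  expect_equal(miss$specificity, 1)
  expect_equal(miss$MCC, 0)              # zero factor under the root
  expect_true("PPV" %in% miss$undefined) # no positive predictions
  expect_true(is.nan(miss$FDR))

  both_empty <- confusion_metrics(zero, zero, evalm)
  expect_equal(both_empty$DSC, 1)        # empty/empty agreement

  allref <- confusion_metrics(evalm, evalm, evalm)
  expect_true(is.nan(allref$specificity))  # TN + FP = 0
  expect_error(confusion_metrics(zero, ref, zero), "empty evaluation mask")
  expect_error(confusion_metrics(zero, ref, array(1, c(4, 4, 3))), "geometry")
})

test_that("hemisphere restriction preserves counts of an ipsilateral reference", {
  s <- generate_subject(small_config(), "h", seed = 18)
  ref <- s$reference_masks$core           # wholly ipsilateral by construction
  pred <- adc_threshold(s)
  whole <- confusion_metrics(pred, ref, s$brain_mask)
  ipsi <- confusion_metrics(pred, ref, s$hemisphere_mask == 1, "ipsilateral")
  expect_identical(whole$TP, ipsi$TP)
  expect_identical(whole$FN, ipsi$FN)
  expect_lte(ipsi$FP, whole$FP)
  expect_identical(metrics_table(list(w = whole, i = ipsi))$mask_name,
                   c("whole_brain", "ipsilateral"))
})

test_that("lesion volumes scale with voxel size and partition by hemisphere", {
  grid <- c(5, 5, 2)
  map <- array(0, grid); map[1:10] <- 1
  expect_equal(lesion_volume(map, c(0.25, 0.25, 1)), 0.625)
  expect_equal(lesion_volume(array(0, grid), c(1, 1, 1)), 0)
  s <- generate_subject(small_config(), "v", seed = 19)
  m <- adc_threshold(s)
  whole <- lesion_volume(m, s$voxel_dims)
  parts <- lesion_volume(m, s$voxel_dims, s$hemisphere_mask == 1) +
           lesion_volume(m, s$voxel_dims, s$hemisphere_mask == 2)
  expect_equal(whole, parts)
})

test_that("Pearson correlation matches hand computation and guards input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  hand <- pearson_correlation(x, c(2, 1, 4, 3))
  expect_equal(hand$r, 0.6)  # product-moment formula by hand: 3/5
  expect_equal(hand$n, 4)
  expect_error(pearson_correlation(x, rep(1, 4)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(1:4, 1:5), "length")
})

test_that("joint probability maps average binary segmentations on a lattice", {
  grid <- c(3, 3, 2)
  a <- array(0, grid); a[1, 1, 1] <- 1; a[2, 2, 1] <- 1
  b <- array(0, grid); b[1, 1, 1] <- 1
  expect_identical(joint_probability_map(list(a)), a)
  j <- joint_probability_map(list(a, b))
  expect_equal(j[1, 1, 1], 1)
  expect_equal(j[2, 2, 1], 0.5)
  maps <- list(a, b, a, b, a)
  jj <- joint_probability_map(maps)
  expect_true(all(abs(jj * 5 - round(jj * 5)) < 1e-12))  # {0, 1/5, ..., 1}
  expect_error(joint_probability_map(list(a, array(0, c(3, 3, 3)))), "geometry")
})

test_that("scattered false positives count and shrink under median filtering", {
  grid <- c(12, 12, 6)
  expect_equal(scattered_false_positive_count(array(0, grid)), 0)
  m <- array(0, grid)
  m[cbind(c(2, 5, 8, 11, 3, 6, 9), c(2, 5, 8, 11, 9, 3, 6), c(2, 3, 4, 5, 2, 3, 4))] <- 1
  expect_equal(scattered_false_positive_count(m), 7)
  set.seed(20)
  for (i in 1:3) {
    noise <- array(rbinom(prod(grid), 1, 0.02), grid)
    expect_lte(scattered_false_positive_count(median_filter_labels(noise, 3)),
               scattered_false_positive_count(noise))
  }
})
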