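test_that("single-component fit recovers the sample moments", {
  set.seed(1)
  x <- cbind(rnorm(2000), rnorm(2000))
  fit <- fit_gmm(x, K = 1, seed = 1)
  expect_equal(fit$means[1, ], colMeans(x), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$weights, 1)
  expect_true(all(fit$labels == 1))
})

test_that("EM recovers two well-separated planted clusters", {
  set.seed(2)
  n1 <- 5000; n2 <- 500
  x <- rbind(cbind(rnorm(n1, 0, 1), rnorm(n1, 0, 1)),
             cbind(rnorm(n2, -3, 0.7), rnorm(n2, 2.5, 0.9)))
  planted <- rep(1:2, c(n1, n2))
  fit <- fit_gmm(x, K = 2, seed = 3)
  # match components to planted clusters by their means
  perm <- if (fit$means[1, 1] > fit$means[2, 1]) 1:2 else 2:1
  emp1 <- colMeans(x[planted == 1, ]); emp2 <- colMeans(x[planted == 2, ])
  expect_lt(max(abs(fit$means[perm[1], ] - emp1)), 0.1)
  expect_lt(max(abs(fit$means[perm[2], ] - emp2)), 0.1)
  agree <- mean((fit$labels == perm[2]) == (planted == 2))
  expect_gte(agree, 0.99)
  # partition property: one hard label each, counts sum to n
  expect_equal(sum(fit$counts), nrow(x))
  expect_true(fit$converged)
})

test_that("fits are deterministic given the seed", {
  set.seed(4)
  x <- rbind(cbind(rnorm(800), rnorm(800)), cbind(rnorm(80, 4), rnorm(80, 4)))
  f1 <- fit_gmm(x, 2, seed = 7)
  f2 <- fit_gmm(x, 2, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$labels, f2$labels)
  expect_identical(predict(f1, x), f1$labels)
})

test_that("stroke component selection follows the raw-mean signature", {
  # the only reduced-ADC / elevated-T2W candidate wins
  fit <- fake_gmm_fit(mu_adc = c(800, 500), mu_t2w = c(90, 130))
  expect_identical(select_stroke_component(fit), 2L)

  # five components: argmax of the T2W/ADC ratio, verified by brute force
  mu_adc <- c(820, 500, 760, 905, 650)
  mu_t2w <- c(88, 131, 127, 95, 101)
  fit5 <- fake_gmm_fit(mu_adc, mu_t2w)
  brute <- which.max(vapply(1:5, function(k) mu_t2w[k] / mu_adc[k], 0))
  expect_identical(select_stroke_component(fit5), as.integer(brute))
  expect_identical(brute, 2L)  # has both min ADC and max T2W

  # exact ratio tie breaks to the lower component index
  tie <- fake_gmm_fit(mu_adc = c(500, 1000), mu_t2w = c(100, 200))
  expect_identical(select_stroke_component(tie), 1L)

  # alternative orderings agree on clean geometry
  expect_identical(select_stroke_component(fit5, rule = "adc_over_t2w"), 2L)
  expect_identical(select_stroke_component(fit5, rule = "lexicographic"), 2L)

  # degenerate cases
  neg <- fake_gmm_fit(mu_adc = c(-1, 500), mu_t2w = c(90, 130))
  expect_error(select_stroke_component(neg), "degenerate-component")
  emp <- fake_gmm_fit(mu_adc = c(800, 500, NA), mu_t2w = c(90, 130, NA),
                      labels = rep(1:2, c(10, 5)))
  expect_warning(sel <- select_stroke_component(emp), "empty")
  expect_identical(sel, 2L)
})

test_that("selection depends only on un-normalized member means", {
  fit <- fake_gmm_fit(mu_adc = c(800, 500), mu_t2w = c(90, 130))
  rescaled <- fit
  rescaled$means <- fit$means * 10 + 3   # any affine change of fitting space
  rescaled$covariances <- lapply(fit$covariances, function(S) S * 100)
  expect_identical(select_stroke_component(rescaled),
                   select_stroke_component(fit))
})

test_that("contralateral fraction counts the stroke cluster's contralateral share", {
  fit <- fake_gmm_fit(mu_adc = c(800, 500), mu_t2w = c(90, 130),
                      labels = rep(1:2, c(20, 10)))
  fit$stroke_component <- 2L
  hemi <- c(rep(1, 20), rep(1, 8), rep(2, 2))  # 2 of 10 stroke voxels contra
  expect_equal(contralateral_fraction(fit, hemi), 0.2)
  expect_equal(contralateral_fraction(fit, rep(1, 30)), 0)
  # alternative denominator: share of all contralateral voxels captured
  expect_equal(contralateral_fraction(fit, hemi, denominator = "contralateral"), 1)

  none <- fit; none$stroke_component <- NA_integer_
  expect_error(contralateral_fraction(none, hemi), "stroke_component")
  empty <- fake_gmm_fit(mu_adc = c(800, 500), mu_t2w = c(90, 130),
                        labels = rep(1, 30))
  empty$stroke_component <- 2L
  expect_error(contralateral_fraction(empty, rep(1, 30)), "undefined-fraction")
})

test_that("plateau rule stops at the first insignificant improvement", {
  expect_identical(select_plateau(c(0.30, 0.18, 0.06, 0.055, 0.054),
                                  K = 2:6, eps = 0.01), 4L)
  expect_identical(select_plateau(rep(0.08, 5), K = 2:6, eps = 0.01), 2L)
  expect_warning(k <- select_plateau(c(0.5, 0.4, 0.3, 0.2, 0.1),
                                     K = 2:6, eps = 0.01), "no .*plateau")
  expect_identical(k, 6L)
})

test_that("model-order scan labels the stroke cluster on phantom cohorts", {
  cfg <- small_config()
  coh <- generate_cohort(cfg, seed = 21)
  tab <- to_feature_table(coh$training)
  norm <- apply_recipe(make_recipe("population_zscore", tab), tab)
  scan <- select_model_order(norm, K_range = 2:4, eps = 0.01, seed = 5,
                             raw = tab, fit_subsample = 5000)
  expect_s3_class(scan, "model_order_scan")
  expect_true(scan$chosen_k %in% 2:4)
  fit <- scan$chosen_fit
  expect_false(is.na(fit$stroke_component))
  # the stroke cluster recovers the pooled planted cores
  core <- unlist(lapply(coh$training, function(s)
    s$reference_masks$core[s$brain_mask == 1] == 1))
  in_cluster <- fit$labels == fit$stroke_component
  expect_gte(sum(in_cluster & core) / sum(core), 0.95)
  # scan JSON serialization round-trips the chosen order
  path <- tempfile(fileext = ".json")
  write_scan_json(scan, path)
  expect_equal(jsonlite::read_json(path)$chosen_k, scan$chosen_k)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(require(mclust, quietly = TRUE))
  set.seed(6)
  x <- rbind(cbind(rnorm(3000, 0, 1), rnorm(3000, 0, 1)),
             cbind(rnorm(300, -3.2, 0.8), rnorm(300, 2.4, 1)))
  fit <- fit_gmm(x, 2, seed = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  perm <- if (fit$means[1, 1] < fit$means[2, 1]) 1:2 else 2:1
  mperm <- if (mc$parameters$mean[1, 1] < mc$parameters$mean[1, 2]) 1:2 else 2:1
  expect_equal(fit$means[perm[1], ],
               unname(mc$parameters$mean[, mperm[1]]), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(fit$means[perm[2], ],
               unname(mc$parameters$mean[, mperm[2]]), tolerance = 0.05,
               ignore_attr = TRUE)
  agree <- mean((fit$labels == perm[2]) == (mc$classification == mperm[2]))
  expect_gte(agree, 0.99)
})
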