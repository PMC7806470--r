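# Shared fixtures and independent oracles, all generated in code.

# small, fast phantom for unit tests (~2.4k in-brain voxels per subject)
small_config <- function(...) {
  defaults <- list(grid = c(32, 32, 12), voxel_dims = c(0.5, 0.5, 1.5),
                   n_train = 3, n_test = 2,
                   brain_radii = c(12, 12, 4),
                   lesion_center = c(10, 16, 6), lesion_radii = c(3, 3, 2),
                   lesion_center_jitter = c(1, 1, 0), lesion_radii_jitter = 0,
                   artifact_center = c(23, 16, 6), artifact_radii = c(2, 2, 1),
                   artifact_radii_jitter = 0)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# hand-built 2x2x2 subject with fully controlled values
tiny_subject <- function(adc_vals = 800, t2w_vals = 90) {
  grid <- c(2, 2, 2)
  brain <- array(1, grid)
  hemi <- array(c(1, 2), grid)  # alternates along i: i=1 ipsi, i=2 contra
  subject_dataset("tiny",
                  adc = array(adc_vals, grid), t2w = array(t2w_vals, grid),
                  brain_mask = brain, hemisphere_mask = hemi,
                  voxel_dims = c(1, 1, 1))
}

# construct a gmm_fit skeleton with prescribed member statistics, for testing
# selection logic in isolation from EM
fake_gmm_fit <- function(mu_adc, mu_t2w, counts = NULL, labels = NULL) {
  K <- length(mu_adc)
  if (is.null(labels)) labels <- rep(seq_len(K), times = counts %||% rep(10, K))
  counts <- tabulate(labels, nbins = K)
  structure(list(K = K, weights = counts / sum(counts),
                 means = matrix(0, K, 2),
                 covariances = rep(list(diag(2)), K),
                 labels = labels, counts = counts,
                 mu_adc = mu_adc, mu_t2w = mu_t2w,
                 loglik = 0, n_iter = 1L, converged = TRUE, seed = 1L,
                 stroke_component = NA_integer_),
            class = "gmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive per-voxel confusion-metric oracle: explicit loop, no vectorization,
# independent of the package implementation
naive_confusion <- function(pred, ref, eval_mask) {
  TP <- FP <- FN <- TN <- 0L
  for (i in seq_along(pred)) {
    if (eval_mask[i] <= 0) next
    p <- pred[i] > 0; r <- ref[i] > 0
    if (p && r) TP <- TP + 1L
    else if (p && !r) FP <- FP + 1L
    else if (!p && r) FN <- FN + 1L
    else TN <- TN + 1L
  }
  sdiv <- function(a, b) if (b == 0) NaN else a / b
  dsc <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
  fac <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(fac == 0)) 0 else (TP * TN - FP * FN) / sqrt(prod(fac))
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       accuracy = sdiv(TP + TN, TP + FP + FN + TN),
       sensitivity = sdiv(TP, TP + FN), specificity = sdiv(TN, TN + FP),
       PPV = sdiv(TP, TP + FP), NPV = sdiv(TN, TN + FN),
       FDR = if (TP + FP == 0) NaN else 1 - sdiv(TP, TP + FP),
       FPR = if (TN + FP == 0) NaN else 1 - sdiv(TN, TN + FP),
       DSC = dsc, MCC = mcc)
}

# naive sliding-window binary median filter (majority vote), explicit loops
naive_median_filter <- function(map, kernel) {
  d <- dim(map); r <- (kernel - 1) / 2
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    cnt <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3] && map[ii, jj, kk] > 0) cnt <- cnt + 1
    }
    out[i, j, k] <- as.numeric(2 * cnt > kernel^3)
  }
  out
}

# 4x4x2 printed toy volume with hand-counted threshold outcomes.
# Hemispheres: i in 1:2 ipsilateral (1), i in 3:4 contralateral (2).
# ADC slab (all 32 voxels in-brain), values chosen so that exactly 5 voxels
# lie strictly below 680 (one voxel sits exactly at 680 and must NOT count):
#   slice z=1:          slice z=2:
#     500 700 800 900     679 680 800 760
#     600 720 810 910     400 690 820 770
#     650 730 830 920     700 710 840 780
#     700 740 850 930     705 715 860 790
# -> below 680: 500, 600, 650, 679, 400  (n = 5; ipsi: 500, 600, 679, 400;
#    contra: 650)
# T2W: all 16 contralateral voxels (i = 3, 4) equal 100 -> contralateral mean
# 100, cutoff 125% -> 125. Ipsilateral values include exactly three voxels
# strictly above 125 (130, 126, 200) and one voxel exactly at 125 which must
# NOT count:
#   slice z=1 (i=1,2 rows): 90 130 ; 95 126 ; 100 125 ; 105 110
#   slice z=2 (i=1,2 rows): 80 200 ; 85 115 ; 90 116 ; 95 117
toy_threshold_subject <- function() {
  grid <- c(4, 4, 2)
  adc <- array(0, grid)
  adc[, , 1] <- matrix(c(500, 700, 800, 900,
                         600, 720, 810, 910,
                         650, 730, 830, 920,
                         700, 740, 850, 930), 4, 4, byrow = TRUE)
  adc[, , 2] <- matrix(c(679, 680, 800, 760,
                         400, 690, 820, 770,
                         700, 710, 840, 780,
                         705, 715, 860, 790), 4, 4, byrow = TRUE)
  t2w <- array(100, grid)  # contralateral side stays at 100 everywhere
  t2w[1:2, , 1] <- matrix(c(90, 130,
                            95, 126,
                            100, 125,
                            105, 110), 2, 4)
  t2w[1:2, , 2] <- matrix(c(80, 200,
                            85, 115,
                            90, 116,
                            95, 117), 2, 4)
  hemi <- array(0, grid)
  hemi[1:2, , ] <- 1; hemi[3:4, , ] <- 2
  subject_dataset("toy", adc = adc, t2w = t2w,
                  brain_mask = array(1, grid), hemisphere_mask = hemi,
                  voxel_dims = c(1, 1, 1))
}
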