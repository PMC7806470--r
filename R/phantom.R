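#' Configuration for the synthetic stroke phantom
#'
#' The phantom emulates the two-channel voxel-feature structure of acute
#' middle-cerebral-artery-occlusion imaging: an ellipsoidal brain split by a
#' midline into an ipsilateral (1) and contralateral (2) hemisphere, healthy
#' tissue with ADC mostly in the 500-1100 (1e-6 mm^2/s) range and T2W mostly
#' in the 50-125 a.u. range, and an ellipsoidal ischemic core with reduced
#' ADC (below ~600) and elevated T2W restricted to the ipsilateral side.
#' Optional confounders reproduce the failure modes the framework is designed
#' to separate: a vasogenic edema rim (elevated T2W, normal ADC) around the
#' core, and a low-ADC artifact blob with normal T2W placed contralaterally.
#' A multiplicative/additive T2W scale shift emulates a change of scanner or
#' field strength (T2W is not quantitative; ADC is and never shifts).
#'
#' Channel distributions are i.i.d. Gaussian per voxel with means placed
#' inside the empirical ranges above: healthy ADC N(800, 80), healthy T2W
#' N(90, 15), stroke ADC N(500, 60), stroke T2W N(130, 15), edema T2W
#' N(130, 15) over healthy ADC, artifact ADC N(500, 60) under healthy T2W.
#' ADC draws are clipped at 0.
#'
#' @param grid integer triple, grid shape. Default 64 x 64 x 24 (rat-like).
#' @param voxel_dims mm per voxel edge. Default 0.25 x 0.25 x 1.0.
#' @param n_train,n_test cohort sizes. Defaults 12 and 20.
#' @param brain_radii ellipsoid semi-axes of the brain mask, in voxels.
#' @param healthy_adc,healthy_t2w,stroke_adc,stroke_t2w,edema_t2w,artifact_adc
#'   length-2 vectors `c(mean, sd)` of the generating normals.
#' @param lesion_center,lesion_radii core ellipsoid, voxel coordinates;
#'   must lie entirely in hemisphere 1.
#' @param lesion_center_jitter,lesion_radii_jitter per-axis uniform-integer
#'   jitter bounds applied per subject by [generate_cohort()].
#' @param edema_width rim thickness in voxels added to the core radii.
#' @param include_edema,include_artifact confounder flags (default off).
#' @param artifact_center,artifact_radii,artifact_radii_jitter low-ADC
#'   artifact blob (default in hemisphere 2).
#' @param t2w_scale_shift `c(scale, offset)` applied to T2W by
#'   [apply_scanner_shift()] when simulating another scanner; default
#'   identity.
#' @param smooth_sigma optional Gaussian smoothing (voxels) of each channel;
#'   0 disables (the framework is strictly voxel-wise, so spatial texture is
#'   not required).
#' @param seed default master seed for [generate_cohort()].
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(64, 64, 24),
                           voxel_dims = c(0.25, 0.25, 1.0),
                           n_train = 12, n_test = 20,
                           brain_radii = c(26, 26, 9),
                           healthy_adc = c(800, 80), healthy_t2w = c(90, 15),
                           stroke_adc = c(500, 60), stroke_t2w = c(130, 15),
                           edema_t2w = c(130, 15), artifact_adc = c(500, 60),
                           lesion_center = c(19, 32, 12),
                           lesion_radii = c(7, 7, 4),
                           lesion_center_jitter = c(2, 2, 1),
                           lesion_radii_jitter = 1,
                           edema_width = 2,
                           include_edema = FALSE, include_artifact = FALSE,
                           artifact_center = c(46, 32, 12),
                           artifact_radii = c(3, 3, 2),
                           artifact_radii_jitter = 1,
                           t2w_scale_shift = c(1, 0),
                           smooth_sigma = 0,
                           seed = 20240101) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$grid) == 3, all(cfg$grid >= 8),
            length(cfg$voxel_dims) == 3, all(cfg$voxel_dims > 0),
            cfg$n_train >= 1, cfg$n_test >= 0)
  for (nm in c("healthy_adc", "healthy_t2w", "stroke_adc", "stroke_t2w",
               "edema_t2w", "artifact_adc")) {
    p <- cfg[[nm]]
    if (length(p) != 2 || p[2] <= 0) stop("parameter error: ", nm, " must be c(mean, sd > 0)")
  }
  if (cfg$stroke_adc[1] >= cfg$healthy_adc[1]) {
    stop("parameter error: stroke ADC mean must be below healthy ADC mean")
  }
  if (cfg$stroke_t2w[1] <= cfg$healthy_t2w[1]) {
    stop("parameter error: stroke T2W mean must exceed healthy T2W mean")
  }
  if (cfg$t2w_scale_shift[1] <= 0) stop("parameter error: T2W scale must be > 0")
  class(cfg) <- "phantom_config"
  cfg
}

#' Human-like phantom preset
#'
#' Coarser clinical grid (96 x 96 x 24 at 1 x 1 x 5 mm) with a T2W scale
#' shift emulating acquisition at a different field strength.
#'
#' @param ... overrides passed to [phantom_config()].
#' @export
phantom_config_human <- function(...) {
  defaults <- list(grid = c(96, 96, 24), voxel_dims = c(1, 1, 5),
                   brain_radii = c(40, 40, 9),
                   lesion_center = c(28, 48, 12), lesion_radii = c(10, 10, 4),
                   artifact_center = c(70, 48, 12),
                   t2w_scale_shift = c(2, 10))
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_config, args)
}

# voxels of an ellipsoid as a logical array on `grid`
ellipsoid_mask <- function(grid, center, radii) {
  i <- seq_len(grid[1]); j <- seq_len(grid[2]); k <- seq_len(grid[3])
  di <- ((i - center[1]) / radii[1])^2
  dj <- ((j - center[2]) / radii[2])^2
  dk <- ((k - center[3]) / radii[3])^2
  outer(outer(di, dj, "+"), dk, "+") <= 1
}

#' Generate one synthetic subject
#'
#' @param config a [phantom_config()].
#' @param subject_id character id.
#' @param seed integer seed; the subject is a pure function of
#'   (config, seed).
#' @return a [subject_dataset()] with reference masks `"core"` (the planted
#'   ischemic core), `"EGT"` (identical to `"core"` by construction) and
#'   `"core_plus_edema"`.
#' @export
generate_subject <- function(config, subject_id, seed) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  center <- (grid + 1) / 2
  brain <- ellipsoid_mask(grid, center, config$brain_radii)
  # midline plane along the first axis: hemisphere 1 (ipsilateral) on the
  # low-index side, 2 (contralateral) on the high side
  iidx <- slice.index(array(0, grid), 1)
  hemi <- array(0L, grid)
  hemi[brain & iidx <= center[1]] <- 1L
  hemi[brain & iidx > center[1]] <- 2L

  core <- ellipsoid_mask(grid, config$lesion_center, config$lesion_radii)
  if (any(core & hemi != 1L)) {
    stop("geometry error: lesion ellipsoid is not contained in hemisphere 1 ",
         "of the brain mask")
  }
  rim <- array(FALSE, grid)
  if (config$include_edema) {
    rim <- ellipsoid_mask(grid, config$lesion_center,
                          config$lesion_radii + config$edema_width) & !core & brain
  }
  artifact <- array(FALSE, grid)
  if (config$include_artifact) {
    artifact <- ellipsoid_mask(grid, config$artifact_center, config$artifact_radii) & brain
    artifact <- artifact & !core & !rim
  }

  n <- prod(grid)
  with_seed(seed, {
    adc <- array(stats::rnorm(n, config$healthy_adc[1], config$healthy_adc[2]), grid)
    t2w <- array(stats::rnorm(n, config$healthy_t2w[1], config$healthy_t2w[2]), grid)
    nc <- sum(core)
    adc[core] <- stats::rnorm(nc, config$stroke_adc[1], config$stroke_adc[2])
    t2w[core] <- stats::rnorm(nc, config$stroke_t2w[1], config$stroke_t2w[2])
    if (any(rim)) {
      t2w[rim] <- stats::rnorm(sum(rim), config$edema_t2w[1], config$edema_t2w[2])
    }
    if (any(artifact)) {
      adc[artifact] <- stats::rnorm(sum(artifact), config$artifact_adc[1],
                                    config$artifact_adc[2])
    }
  })
  if (config$smooth_sigma > 0) {
    adc <- smooth_volume(adc, config$smooth_sigma)
    t2w <- smooth_volume(t2w, config$smooth_sigma)
  }
  adc[adc < 0] <- 0
  adc[!brain] <- 0; t2w[!brain] <- 0

  subject_dataset(subject_id,
                  adc = adc, t2w = t2w,
                  brain_mask = array(as.numeric(brain), grid),
                  hemisphere_mask = array(as.numeric(hemi), grid),
                  voxel_dims = config$voxel_dims,
                  reference_masks = list(
                    core = array(as.numeric(core), grid),
                    EGT = array(as.numeric(core), grid),
                    core_plus_edema = array(as.numeric(core | rim), grid)))
}

#' Generate a seeded training/testing cohort
#'
#' Per-subject seeds are derived deterministically from the master seed and
#' the subject's position, so each subject's volumes are reproducible in
#' isolation. Lesion center and radii (and artifact radii, when enabled) are
#' jittered per subject within the configured bounds.
#'
#' @param config a [phantom_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @return list with elements `training` and `testing`, each a list of
#'   [subject_dataset()]s.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"), config$n_test >= 1)
  make <- function(role, i) {
    id <- sprintf("%s%02d", role, i)
    sseed <- derive_seed(seed, paste0("subject-", id))
    scfg <- jitter_lesion(config, derive_seed(sseed, "jitter"))
    generate_subject(scfg, id, sseed)
  }
  list(training = lapply(seq_len(config$n_train), function(i) make("train", i)),
       testing = lapply(seq_len(config$n_test), function(i) make("test", i)))
}

jitter_lesion <- function(config, seed) {
  with_seed(seed, {
    cj <- config$lesion_center_jitter
    rj <- config$lesion_radii_jitter
    config$lesion_center <- config$lesion_center +
      vapply(cj, function(b) if (b > 0) sample(-b:b, 1) else 0L, numeric(1))
    config$lesion_radii <- pmax(2, config$lesion_radii +
      if (rj > 0) sample(-rj:rj, 1) else 0L)
    if (config$include_artifact && config$artifact_radii_jitter > 0) {
      config$artifact_radii <- pmax(1, config$artifact_radii +
        sample(-config$artifact_radii_jitter:config$artifact_radii_jitter, 1))
    }
  })
  config
}

#' Apply a multiplicative/additive scanner shift to the T2W channel
#'
#' T2W intensities are not quantitative; a change of scanner or field
#' strength rescales them. ADC is quantitative and is never shifted.
#'
#' @param subject a [subject_dataset()].
#' @param scale multiplicative factor, > 0.
#' @param offset additive offset.
#' @return a new subject with `t2w <- scale * t2w + offset` inside the brain
#'   mask; ADC and all masks unchanged.
#' @export
apply_scanner_shift <- function(subject, scale, offset = 0) {
  stopifnot(inherits(subject, "subject_dataset"))
  if (scale <= 0) stop("parameter error: scale must be > 0")
  t2w <- subject$t2w
  inb <- subject$brain_mask == 1
  t2w[inb] <- scale * t2w[inb] + offset
  subject$t2w <- t2w
  subject
}

# separable Gaussian smoothing, truncated at 3 sigma
smooth_volume <- function(vol, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  for (axis in 1:3) {
    vol <- apply(vol, setdiff(1:3, axis), function(v) {
      as.numeric(stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)), k,
                               sides = 2))[(r + 1):(r + length(v))]
    })
    vol <- aperm(vol, order(c(axis, setdiff(1:3, axis))))
  }
  vol
}
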