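#' Construct a validated subject dataset
#'
#' A subject dataset bundles one subject's co-registered ADC map (units of
#' 1e-6 mm^2/s, so a cutoff of 680e-6 mm^2/s is the number 680), T2-weighted
#' volume (arbitrary units), brain mask, hemisphere mask and voxel dimensions,
#' plus any reference segmentations (estimated ground truth, manual ROIs,
#' histology-matched masks).
#'
#' The hemisphere mask is ternary: 0 outside the brain, 1 ipsilateral (the
#' occluded side, declared upstream, never inferred), 2 contralateral. The
#' contralateral hemisphere acts as the lesion-free negative control
#' throughout the framework.
#'
#' @param subject_id character scalar.
#' @param adc,t2w 3-D numeric arrays on a common grid.
#' @param brain_mask 3-D array of 0/1.
#' @param hemisphere_mask 3-D array of 0/1/2; nonzero exactly where
#'   `brain_mask == 1`.
#' @param voxel_dims numeric triple, voxel edge lengths in mm.
#' @param reference_masks optional named list of 3-D binary arrays, each a
#'   subset of the brain mask (e.g. `"EGT"`, `"core"`, `"manual_24h"`).
#' @return an object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, adc, t2w, brain_mask, hemisphere_mask,
                            voxel_dims, reference_masks = list()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1)
  adc <- as_volume(adc); t2w <- as_volume(t2w)
  brain_mask <- as_volume(brain_mask); hemisphere_mask <- as_volume(hemisphere_mask)
  dims <- dim(adc)
  for (v in list(t2w, brain_mask, hemisphere_mask)) {
    if (!identical(dim(v), dims)) {
      stop("geometry error: all volumes must share one grid shape (",
           paste(dims, collapse = "x"), ")")
    }
  }
  if (!all(brain_mask %in% c(0, 1))) {
    stop("validation error: brain_mask must be binary")
  }
  if (!all(hemisphere_mask %in% c(0, 1, 2))) {
    stop("validation error: hemisphere mask values must lie in {0, 1, 2}")
  }
  if (!all((hemisphere_mask > 0) == (brain_mask == 1))) {
    stop("validation error: hemisphere_mask must be nonzero exactly on the brain mask")
  }
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3 || any(!is.finite(voxel_dims)) || any(voxel_dims <= 0)) {
    stop("validation error: voxel_dims must be three strictly positive numbers")
  }
  inb <- brain_mask == 1
  if (any(!is.finite(adc[inb])) || any(adc[inb] < 0)) {
    stop("validation error: in-brain ADC values must be finite and >= 0")
  }
  if (length(reference_masks)) {
    if (is.null(names(reference_masks)) || any(names(reference_masks) == "")) {
      stop("validation error: reference masks must be named")
    }
    reference_masks <- lapply(reference_masks, as_volume)
    for (nm in names(reference_masks)) {
      m <- reference_masks[[nm]]
      if (!identical(dim(m), dims)) {
        stop("geometry error: reference mask '", nm, "' is not on the subject grid")
      }
      if (!all(m %in% c(0, 1))) {
        stop("validation error: reference mask '", nm, "' must be binary")
      }
      if (any(m == 1 & !inb)) {
        stop("validation error: reference mask '", nm, "' extends outside the brain mask")
      }
    }
  }
  structure(list(subject_id = subject_id, adc = adc, t2w = t2w,
                 brain_mask = brain_mask, hemisphere_mask = hemisphere_mask,
                 voxel_dims = voxel_dims, reference_masks = reference_masks),
            class = "subject_dataset")
}

as_volume <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  if (is.null(dim(x)) || length(dim(x)) != 3) {
    stop("geometry error: volumes must be 3-D arrays")
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("subject_dataset '", x$subject_id, "': grid ",
      paste(dim(x$adc), collapse = "x"), ", voxel ",
      paste(x$voxel_dims, collapse = "x"), " mm, ",
      sum(x$brain_mask), " in-brain voxels, references: ",
      if (length(x$reference_masks)) paste(names(x$reference_masks), collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Load a subject from NIfTI files
#'
#' Reads co-registered ADC, T2W, brain-mask and hemisphere-mask volumes and
#' validates their geometry (grid shape, voxel dimensions, orientation).
#'
#' @param adc_path,t2w_path,brain_mask_path,hemisphere_mask_path NIfTI files
#'   (`.nii` or `.nii.gz`).
#' @param reference_paths optional named character vector of NIfTI files with
#'   reference segmentations.
#' @param subject_id subject identifier; defaults to the ADC file stem.
#' @return a [subject_dataset()].
#' @export
load_subject <- function(adc_path, t2w_path, brain_mask_path, hemisphere_mask_path,
                         reference_paths = NULL, subject_id = NULL) {
  paths <- c(adc = adc_path, t2w = t2w_path, brain = brain_mask_path,
             hemi = hemisphere_mask_path, reference_paths)
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)
  imgs <- lapply(paths, RNifti::readNifti)
  hdr0 <- RNifti::niftiHeader(imgs[[1]])
  for (i in seq_along(imgs)[-1]) {
    hdr <- RNifti::niftiHeader(imgs[[i]])
    if (!identical(dim(imgs[[i]]), dim(imgs[[1]]))) {
      stop("geometry error: '", paths[i], "' grid ",
           paste(dim(imgs[[i]]), collapse = "x"), " does not match '",
           paths[1], "' grid ", paste(dim(imgs[[1]]), collapse = "x"))
    }
    if (max(abs(hdr$pixdim[2:4] - hdr0$pixdim[2:4])) > 1e-5 ||
        max(abs(unlist(hdr[c("srow_x", "srow_y", "srow_z")]) -
                unlist(hdr0[c("srow_x", "srow_y", "srow_z")]))) > 1e-4) {
      stop("geometry error: '", paths[i], "' voxel dimensions or affine ",
           "disagree with '", paths[1], "'")
    }
  }
  refs <- list()
  if (!is.null(reference_paths)) {
    refs <- lapply(imgs[-(1:4)], function(v) array(as.numeric(v), dim(v)))
    names(refs) <- names(reference_paths)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(adc_path))
  }
  subject_dataset(subject_id,
                  adc = array(as.numeric(imgs[[1]]), dim(imgs[[1]])),
                  t2w = array(as.numeric(imgs[[2]]), dim(imgs[[2]])),
                  brain_mask = array(as.numeric(imgs[[3]]), dim(imgs[[3]])),
                  hemisphere_mask = array(as.numeric(imgs[[4]]), dim(imgs[[4]])),
                  voxel_dims = hdr0$pixdim[2:4],
                  reference_masks = refs)
}

#' Write a volume to NIfTI on a subject's grid
#'
#' @param vol 3-D array (probability map, label map, mask, ...).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param subject the [subject_dataset()] supplying grid and voxel dimensions;
#'   alternatively pass `voxel_dims` directly.
#' @param voxel_dims voxel dimensions in mm, used when `subject` is NULL.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, subject = NULL, voxel_dims = NULL) {
  if (!is.null(subject)) {
    stopifnot(inherits(subject, "subject_dataset"))
    if (!identical(dim(vol), dim(subject$adc))) {
      stop("geometry error: volume is not on the subject grid")
    }
    voxel_dims <- subject$voxel_dims
  }
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  if (!is.null(voxel_dims)) RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write all channels and masks of a subject as NIfTI files
#'
#' @param subject a [subject_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, subject$subject_id)
  out <- c(adc = paste0(stem, "_adc.nii.gz"),
           t2w = paste0(stem, "_t2w.nii.gz"),
           brain_mask = paste0(stem, "_brainmask.nii.gz"),
           hemisphere_mask = paste0(stem, "_hemimask.nii.gz"))
  write_volume(subject$adc, out["adc"], subject)
  write_volume(subject$t2w, out["t2w"], subject)
  write_volume(subject$brain_mask, out["brain_mask"], subject)
  write_volume(subject$hemisphere_mask, out["hemisphere_mask"], subject)
  for (nm in names(subject$reference_masks)) {
    p <- paste0(stem, "_ref_", nm, ".nii.gz")
    write_volume(subject$reference_masks[[nm]], p, subject)
    out[paste0("ref_", nm)] <- p
  }
  invisible(out)
}
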