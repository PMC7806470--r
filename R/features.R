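#' Flatten subjects into a pooled voxel feature table
#'
#' Every in-brain voxel becomes one observation with two features (ADC, T2W),
#' its hemisphere label, and back-references (subject id, linear voxel index
#' in R's native array order) that allow exact reconstruction of maps in
#' anatomical space. Pooling all training subjects yields the population
#' dataset that the mixture model is fitted to.
#'
#' @param subjects a `subject_dataset` or list of them.
#' @return a `data.frame` of class `feature_table` with columns `subject_id`,
#'   `voxel_index`, `adc`, `t2w`, `hemisphere`, ordered by subject then voxel
#'   index, and an attribute `provenance` recording per-channel normalization
#'   state (initially `"raw"` for both channels).
#' @export
to_feature_table <- function(subjects) {
  if (inherits(subjects, "subject_dataset")) subjects <- list(subjects)
  stopifnot(length(subjects) >= 1)
  rows <- lapply(subjects, function(s) {
    stopifnot(inherits(s, "subject_dataset"))
    idx <- which(s$brain_mask == 1)
    if (length(idx) == 0) {
      stop("empty-input error: subject '", s$subject_id, "' has an empty brain mask")
    }
    data.frame(subject_id = s$subject_id, voxel_index = idx,
               adc = s$adc[idx], t2w = s$t2w[idx],
               hemisphere = as.integer(s$hemisphere_mask[idx]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "provenance") <- c(adc = "raw", t2w = "raw")
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Feature-table provenance
#'
#' @param table a feature table.
#' @return named character vector with the normalization state of each channel.
#' @export
provenance <- function(table) {
  attr(table, "provenance") %||% c(adc = "raw", t2w = "raw")
}

#' Map per-voxel values back into anatomical space
#'
#' Inverse of [to_feature_table()] for a single subject: places one value per
#' referenced voxel on the subject grid; unreferenced voxels are 0.
#'
#' @param voxel_index linear voxel indices (R array order) within the brain mask.
#' @param values numeric vector, one per index.
#' @param subject the [subject_dataset()] defining the grid.
#' @return 3-D array on the subject grid.
#' @export
map_back <- function(voxel_index, values, subject) {
  stopifnot(inherits(subject, "subject_dataset"),
            length(voxel_index) == length(values))
  field <- array(0, dim(subject$adc))
  if (length(voxel_index)) {
    if (any(voxel_index < 1 | voxel_index > length(field)) ||
        any(subject$brain_mask[voxel_index] != 1)) {
      stop("index error: rows reference voxels outside the subject's brain mask")
    }
    field[voxel_index] <- values
  }
  field
}

#' Extract one subject's rows from a pooled feature table
#'
#' @param table a feature table.
#' @param subject_id subject to extract.
#' @return the subject's rows, original order preserved.
#' @export
subject_rows <- function(table, subject_id) {
  table[table$subject_id == subject_id, , drop = FALSE]
}
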