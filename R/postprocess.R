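#' Median filter for binary label maps
#'
#' 3-D majority vote over a cubic kernel: a voxel is stroke in the output iff
#' strictly more than half of the kernel^3 positions centered on it are
#' stroke in the input; positions outside the volume count as non-stroke.
#' Removes the isolated voxel-level false-positive "noise" that spatially
#' blind voxel-wise classification produces, at the cost of eroding
#' single-voxel detail.
#'
#' @param map binary 3-D array.
#' @param kernel odd integer edge length >= 3 (default 3).
#' @return binary 3-D array of the same shape.
#' @export
median_filter_labels <- function(map, kernel = 3) {
  if (length(kernel) != 1 || kernel < 3 || kernel %% 2 != 1) {
    stop("parameter error: kernel must be an odd integer >= 3")
  }
  d <- dim(map)
  if (is.null(d) || length(d) != 3) stop("geometry error: map must be 3-D")
  r <- (kernel - 1) / 2
  pad <- array(0, d + 2 * r)
  pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- as.numeric(map > 0)
  counts <- array(0, d)
  for (dx in 0:(kernel - 1)) for (dy in 0:(kernel - 1)) for (dz in 0:(kernel - 1)) {
    counts <- counts + pad[dx + seq_len(d[1]), dy + seq_len(d[2]),
                           dz + seq_len(d[3])]
  }
  array(as.numeric(2 * counts > kernel^3), d)
}
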