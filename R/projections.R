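# Angiographic frame combination and maximum-intensity projections.

#' Frame-combination specification
#'
#' @param start,end Inclusive 0-based frame indices, `0 <= start <= end`.
#' @param axis Projection axis for the subsequent MIP.
#' @return An object of class `qti_projection_spec`.
#' @export
projection_spec <- function(start, end, axis = 3) {
  if (!(start >= 0 && start <= end)) stop("need 0 <= start <= end")
  structure(list(start = as.integer(start), end = as.integer(end),
                 axis = as.integer(axis)), class = "qti_projection_spec")
}

#' Combine reconstructed frames into an angiographic image
#'
#' Voxel-wise sum of the frame magnitudes over an inclusive 0-based frame
#' range. The flow-designed contrast leaves fast inflowing spins
#' hyperintense in the late frames, so summing the last frames (the
#' package convention for N = 260 is the last 160, indices 100..259)
#' yields vessel-bright angiographic images.
#'
#' @param frames Complex (or real) `n x n x N` array of reconstructed
#'   frames.
#' @param spec A [projection_spec()]; by default the last 160 frames (or
#'   all frames when fewer).
#' @return Nonnegative real `n x n` image.
#' @export
combine_frames <- function(frames, spec = NULL) {
  N <- dim(frames)[3]
  if (is.null(spec)) spec <- projection_spec(max(0, N - 160), N - 1)
  if (spec$end >= N) stop("frame range out of bounds")
  idx <- (spec$start:spec$end) + 1L
  apply(Mod(frames[, , idx, drop = FALSE]), c(1, 2), sum)
}

#' Maximum-intensity projection
#'
#' @param volume Real array (2D or 3D stack).
#' @param axis Axis collapsed by the voxel-wise maximum.
#' @return Projection with that axis removed (a 2D input is returned
#'   as-is when projecting along the missing third axis).
#' @export
mip <- function(volume, axis = 3) {
  d <- dim(volume)
  if (length(d) == 2) {
    if (axis == 3) return(volume)
    d <- c(d, 1)
    volume <- array(volume, d)
  }
  if (!(axis %in% seq_along(d))) stop("invalid projection axis")
  apply(volume, setdiff(seq_along(d), axis), max)
}
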