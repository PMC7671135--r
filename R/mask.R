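# Label-field cleanup before tracing: erode the segmentation to kill
# boundary artifacts, then zero the correlation field outside it so no
# spurious tracts are reconstructed beyond the muscle.

#' Morphological erosion of a label field
#'
#' 6-connected (face-neighbour) erosion applied `iterations` times. The
#' boundary outside the grid counts as background, so each pass peels one
#' voxel layer.
#'
#' @param label An [mt_label()].
#' @param iterations Number of erosion passes (>= 0; 0 is the identity).
#' @return The eroded [mt_label()]; a warning is raised if it is empty.
#' @export
erode_label <- function(label, iterations = 1) {
  stopifnot(inherits(label, "mt_label"))
  if (iterations < 0) abort("iterations must be >= 0")
  x <- label$data != 0
  for (it in seq_len(iterations)) {
    x <- x & shift3(x, 1, +1) & shift3(x, 1, -1) &
      shift3(x, 2, +1) & shift3(x, 2, -1) &
      shift3(x, 3, +1) & shift3(x, 3, -1)
  }
  if (iterations > 0 && !any(x))
    warn("erosion produced an empty label field")
  mt_label(x + 0, label$spacing)
}

# shift a logical array by one voxel along axis, filling with FALSE
shift3 <- function(x, axis, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  if (d[axis] < 2) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  # note: for the two axes not shifted, dst == src == full range
  out
}

#' Mask a correlation field with a label
#'
#' Multiplies the correlation field by the binary label (zero outside the
#' muscle); the orientation field is untouched. Run after [erode_label()]
#' so that segmentation-boundary artifacts cannot seed tracts.
#'
#' @param fields An [mt_fiber_fields()].
#' @param label An [mt_label()] on the same grid.
#' @return Masked [mt_fiber_fields()].
#' @export
apply_mask <- function(fields, label) {
  stopifnot(inherits(fields, "mt_fiber_fields"), inherits(label, "mt_label"))
  if (!identical(dim(fields$correlation), dim(label$data)))
    abort("label shape does not match the fiber fields")
  out <- fields
  out$correlation <- fields$correlation * (label$data != 0)
  out$masked <- TRUE
  out
}
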