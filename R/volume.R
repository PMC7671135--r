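# Core containers: grayscale volume and binary label field on an isotropic
# voxel grid. World coordinates are voxel-center based: 0-based index * spacing
# (micrometres), identically in every module.

#' Construct a grayscale volume
#'
#' An `mt_volume` wraps a 3D numeric array together with its isotropic voxel
#' spacing in micrometres. Voxel `[i, j, k]` (1-based in R) sits at world
#' coordinate `(i-1, j-1, k-1) * spacing` µm; the third array axis is the
#' slice (z) axis.
#'
#' @param data 3D numeric array of finite grayscale values.
#' @param spacing Isotropic voxel edge length in µm; must be positive.
#' @return An object of class `mt_volume`.
#' @export
#' @examples
#' v <- mt_volume(array(0, c(4, 4, 4)), spacing = 43.863)
#' dim(v$data)
mt_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array")
  if (!is.numeric(data) || !all(is.finite(data)))
    abort("volume grayscale values must be finite numerics")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    abort("`spacing` must be a single positive number (µm)")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "mt_volume")
}

#' Construct a binary label field
#'
#' An `mt_label` is a binary mask on the same grid as its companion volume,
#' delimiting one muscle. Values must be 0/1.
#'
#' @param data 3D array of 0/1 values (logical arrays are coerced).
#' @param spacing Isotropic voxel edge length, µm.
#' @return An object of class `mt_label`.
#' @export
mt_label <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array")
  if (is.logical(data) || is.integer(data)) data <- data + 0
  if (!all(data %in% c(0, 1)))
    abort("label field values must be 0 or 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    abort("`spacing` must be a single positive number (µm)")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "mt_label")
}

#' @export
print.mt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mt_volume> %d x %d x %d voxels, spacing %.4g um\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mt_label <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mt_label> %d x %d x %d voxels, spacing %.4g um, %d foreground\n",
              d[1], d[2], d[3], x$spacing, sum(x$data != 0)))
  invisible(x)
}

# shape equality helper used by masking / correlation stages
same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9))
}

#' World coordinates of voxel indices
#'
#' Maps 1-based array indices to world coordinates in µm under the package's
#' voxel-center convention (`(index - 1) * spacing`).
#'
#' @param idx Integer matrix (n x 3) or vector of length 3 of 1-based indices.
#' @param spacing Voxel spacing, µm.
#' @return Numeric matrix (n x 3) of world coordinates in µm.
#' @export
voxel_to_world <- function(idx, spacing) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  (idx - 1) * spacing
}

#' @rdname voxel_to_world
#' @param xyz Numeric matrix (n x 3) of world coordinates, µm.
#' @return For `world_to_voxel`, fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(xyz, spacing) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz / spacing + 1
}
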