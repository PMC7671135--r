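# Cylindrical template construction.
#
# The template models an iodine-bright fascicle core (positive cylinder of
# the outer-cylinder radius) surrounded by the darker perimysial sheath
# (negative annulus out to the mask-cylinder radius). Kernels are zero-mean
# and unit-norm so that template correlation is an intensity-scale-free
# normalized score.

#' Cylinder template parameters
#'
#' @param outer_cylinder_radius Bright core radius, µm. Note: some workflows
#'   quote this setting as "the diameter of a typical fascicle"; to match
#'   that usage, pass the fascicle diameter here.
#' @param cylinder_length Template length, µm.
#' @param angular_sampling Orientation grid step, degrees in `(0, 90]`.
#' @param mask_cylinder_radius Outer radius of the dark annulus, µm;
#'   defaults to 1.5x the core radius.
#' @return A `template_params` list.
#' @export
template_params <- function(outer_cylinder_radius,
                            cylinder_length,
                            angular_sampling = 10,
                            mask_cylinder_radius = 1.5 * outer_cylinder_radius) {
  if (outer_cylinder_radius <= 0) abort("outer_cylinder_radius must be positive")
  if (mask_cylinder_radius < outer_cylinder_radius)
    abort("mask_cylinder_radius must be >= outer_cylinder_radius")
  if (angular_sampling <= 0 || angular_sampling > 90)
    abort("angular_sampling must lie in (0, 90]")
  structure(list(outer_cylinder_radius = outer_cylinder_radius,
                 cylinder_length = cylinder_length,
                 angular_sampling = angular_sampling,
                 mask_cylinder_radius = mask_cylinder_radius),
            class = "template_params")
}

#' Build an oriented cylinder kernel
#'
#' Voxelises the cylinder template along `direction` on the volume grid:
#' `+1` inside the core, `-1` in the sheath annulus, then shifted to zero
#' mean over the support and scaled to unit norm. The kernel array is the
#' tight bounding box of the rotated outer cylinder.
#'
#' @param p A [template_params()].
#' @param spacing Voxel spacing, µm.
#' @param direction Unit 3-vector.
#' @return 3D numeric array with odd dimensions (kernel centre at the
#'   middle voxel); attributes `direction` and `half` (half-extent per axis,
#'   voxels).
#' @export
build_template <- function(p, spacing, direction) {
  stopifnot(inherits(p, "template_params"))
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6) abort("direction must be unit-norm")
  if (p$outer_cylinder_radius < spacing / 2)
    abort("outer_cylinder_radius is below half a voxel: template unresolvable at this spacing")
  if (p$cylinder_length < 2 * spacing)
    abort("cylinder_length must be at least two voxels")
  d <- direction
  hl <- p$cylinder_length / 2
  rm_ <- p$mask_cylinder_radius
  # tight per-axis half-extent of the rotated cylinder (axis +/- hl*d, radius rm)
  half_um <- abs(d) * hl + sqrt(pmax(1 - d^2, 0)) * rm_
  half <- pmax(ceiling(half_um / spacing), 1L)
  if (prod(2 * half + 1) > 2^27)
    abort("template support exceeds any practical volume at this spacing")
  ii <- (-half[1]):half[1]; jj <- (-half[2]):half[2]; kk <- (-half[3]):half[3]
  nx <- length(ii); ny <- length(jj); nz <- length(kk)
  ux <- array(ii * spacing, c(nx, ny, nz))
  uy <- aperm(array(jj * spacing, c(ny, nx, nz)), c(2, 1, 3))
  uz <- aperm(array(kk * spacing, c(nz, nx, ny)), c(2, 3, 1))
  t <- ux * d[1] + uy * d[2] + uz * d[3]
  rad2 <- pmax(ux^2 + uy^2 + uz^2 - t^2, 0)
  core <- abs(t) <= hl & rad2 <= p$outer_cylinder_radius^2
  annulus <- abs(t) <= hl & !core & rad2 <= rm_^2
  k <- array(0, c(nx, ny, nz))
  k[core] <- 1
  k[annulus] <- -1
  supp <- core | annulus
  ns <- sum(supp)
  if (ns < 2) abort("template support is degenerate at this spacing")
  k[supp] <- k[supp] - sum(k[supp]) / ns
  nrm <- sqrt(sum(k^2))
  if (nrm < 1e-12) abort("template is constant over its support")
  k <- k / nrm
  attr(k, "direction") <- d
  attr(k, "half") <- half
  k
}
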