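# Cylinder correlation: sweep the oriented template over the volume and keep,
# per voxel, the best normalized correlation and its orientation.
#
# Each orientation's correlation image is computed by FFT cross-correlation
# of the (reflect-padded) volume with the zero-mean unit-norm kernel, divided
# by the local patch norm over a fixed spherical support (the bounding sphere
# of the template, common to all orientations). By Cauchy-Schwarz the score
# lies in [-1, 1]. The per-voxel max/argmax over the deterministic
# orientation list is the contract; ties keep the earliest orientation.

#' Per-voxel fiber correlation and orientation fields
#'
#' @param correlation 3D array of scores in `[-1, 1]`.
#' @param orientation 4D array (x, y, z, 3) of axial unit vectors.
#' @param spacing Voxel spacing, µm.
#' @param params The [template_params()] used (provenance).
#' @return An `mt_fiber_fields` object.
#' @export
mt_fiber_fields <- function(correlation, orientation, spacing, params = NULL) {
  stopifnot(length(dim(correlation)) == 3L, length(dim(orientation)) == 4L,
            identical(dim(correlation), dim(orientation)[1:3]),
            dim(orientation)[4] == 3L)
  if (!all(is.finite(correlation))) abort("correlation scores must be finite")
  structure(list(correlation = correlation, orientation = orientation,
                 spacing = spacing, params = params),
            class = "mt_fiber_fields")
}

#' @export
print.mt_fiber_fields <- function(x, ...) {
  d <- dim(x$correlation)
  cat(sprintf("<mt_fiber_fields> %d x %d x %d, correlation range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$correlation), max(x$correlation)))
  invisible(x)
}

#' Correlate a cylinder template against a volume
#'
#' Stage (1)-(2) of the tracking workflow: the cylindrical template is
#' propagated through the image over a near-uniform axial orientation set
#' (step `p$angular_sampling` degrees), producing a correlation field (fit
#' likelihood of the template at each voxel) and an orientation field (the
#' best-fit axial direction). Boundaries are handled by reflect padding.
#'
#' @param vol An [mt_volume()].
#' @param p A [template_params()] (all lengths in µm).
#' @param verbose Print per-orientation progress.
#' @return An [mt_fiber_fields()].
#' @export
correlate_volume <- function(vol, p, verbose = FALSE) {
  stopifnot(inherits(vol, "mt_volume"), inherits(p, "template_params"))
  sp <- vol$spacing
  dims <- dim(vol$data)
  dirs <- sample_orientations(p$angular_sampling)
  # analytic per-orientation kernel half-extents, checked against the volume
  # before any kernel is allocated
  hl <- p$cylinder_length / 2
  rm_ <- p$mask_cylinder_radius
  halves <- apply(dirs, 1, function(d)
    pmax(ceiling((abs(d) * hl + sqrt(pmax(1 - d^2, 0)) * rm_) / sp), 1))
  if (any(dims < 2 * apply(halves, 1, max) + 1))
    abort("volume is smaller than the template kernel support")
  kernels <- lapply(seq_len(nrow(dirs)), function(i)
    build_template(p, sp, dirs[i, ]))
  # spherical normalization support: bounding sphere of the template
  rs_um <- sqrt((p$cylinder_length / 2)^2 + p$mask_cylinder_radius^2)
  hb <- rep(ceiling(rs_um / sp), 3)
  pad <- pmax(apply(halves, 1, max), hb)
  pdims <- vapply(dims + 2 * pad, next_good_size, integer(1))
  vpad <- embed_zero(pad_reflect(vol$data, pad), pdims)
  fv <- fft(vpad)
  fv2 <- fft(vpad^2)
  ball <- ball_kernel(hb, rs_um / sp)
  fb <- Conj(fft(embed_kernel(ball, pdims, hb)))
  nb <- sum(ball)
  core_idx <- lapply(1:3, function(a) pad[a] + seq_len(dims[a]))
  s1 <- crop(Re(fft(fv * fb, inverse = TRUE)) / prod(pdims), core_idx)
  s2 <- crop(Re(fft(fv2 * fb, inverse = TRUE)) / prod(pdims), core_idx)
  denom <- sqrt(pmax(s2 - s1^2 / nb, 0))
  ok <- denom > 1e-9 * max(denom)
  best <- array(-Inf, dims)
  arg <- array(1L, dims)
  for (i in seq_len(nrow(dirs))) {
    k <- kernels[[i]]
    fk <- Conj(fft(embed_kernel(k, pdims, attr(k, "half"))))
    num <- crop(Re(fft(fv * fk, inverse = TRUE)) / prod(pdims), core_idx)
    sc <- array(0, dims)
    sc[ok] <- num[ok] / denom[ok]
    sc <- pmin(pmax(sc, -1), 1)
    upd <- sc > best
    best[upd] <- sc[upd]
    arg[upd] <- i
    if (verbose) message(sprintf("orientation %d/%d", i, nrow(dirs)))
  }
  orient <- array(0, c(dims, 3L))
  for (a in 1:3) orient[, , , a] <- array(dirs[arg, a], dims)
  mt_fiber_fields(best, orient, sp, p)
}

#' Write / read fiber fields as NIfTI
#'
#' Persists the correlation field as a scalar NIfTI and the orientation
#' field as a 3-component (4D) NIfTI, so pipeline stages can be run and
#' inspected independently.
#'
#' @param fields An [mt_fiber_fields()].
#' @param correlation_path,orientation_path Output .nii / .nii.gz paths.
#' @return Paths (write) or an [mt_fiber_fields()] (read).
#' @export
write_fiber_fields <- function(fields, correlation_path, orientation_path) {
  stopifnot(inherits(fields, "mt_fiber_fields"))
  write_volume(mt_volume(fields$correlation, fields$spacing), correlation_path)
  arr <- fields$orientation
  attr(arr, "pixdim") <- c(rep(fields$spacing, 3), 1)
  attr(arr, "pixunits") <- "um"
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, orientation_path, version = 2)
  invisible(c(correlation_path, orientation_path))
}

#' @rdname write_fiber_fields
#' @param spacing_override Optional spacing override, µm.
#' @export
read_fiber_fields <- function(correlation_path, orientation_path,
                              spacing_override = NULL) {
  cv <- read_volume(correlation_path, spacing_override)
  oi <- RNifti::readNifti(orientation_path)
  orient <- as.array(oi)
  attributes(orient) <- list(dim = dim(orient))
  mt_fiber_fields(cv$data, orient, cv$spacing)
}

# --- internals ---------------------------------------------------------------

# smallest size >= n whose prime factors are all <= 7 (fast FFT lengths)
next_good_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (f in c(2L, 3L, 5L, 7L)) while (m %% f == 0L) m <- m %/% f
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

pad_reflect <- function(arr, pad) {
  d <- dim(arr)
  idx <- lapply(1:3, function(a) {
    i <- c(rev(seq_len(pad[a]) + 1L), seq_len(d[a]),
           d[a] - seq_len(pad[a]))
    pmin(pmax(i, 1L), d[a])
  })
  arr[idx[[1]], idx[[2]], idx[[3]]]
}

embed_zero <- function(arr, pdims) {
  d <- dim(arr)
  if (all(d == pdims)) return(arr)
  out <- array(0, pdims)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

# place a centred kernel into a pdims array with wrapped (circular) offsets
embed_kernel <- function(k, pdims, half) {
  out <- array(0, pdims)
  d <- dim(k)
  ix <- ((-half[1]):half[1]) %% pdims[1] + 1L
  iy <- ((-half[2]):half[2]) %% pdims[2] + 1L
  iz <- ((-half[3]):half[3]) %% pdims[3] + 1L
  out[ix, iy, iz] <- k
  out
}

crop <- function(arr, idx) arr[idx[[1]], idx[[2]], idx[[3]]]

ball_kernel <- function(half, rad_vox) {
  ii <- (-half[1]):half[1]; jj <- (-half[2]):half[2]; kk <- (-half[3]):half[3]
  nx <- length(ii); ny <- length(jj); nz <- length(kk)
  ux <- array(ii, c(nx, ny, nz))
  uy <- aperm(array(jj, c(ny, nx, nz)), c(2, 1, 3))
  uz <- aperm(array(kk, c(nz, nx, ny)), c(2, 3, 1))
  (ux^2 + uy^2 + uz^2 <= rad_vox^2) + 0
}
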