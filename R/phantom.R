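# Synthetic DiceCT-like phantoms: bright cylindrical fascicles (iodine-stained
# myofiber bundles) separated by darker connective-tissue sheaths, with known
# ground-truth centerlines. Layouts: parallel, bipennate (two mirrored sets
# about a dark central tendon plane), hemiradial (azimuths over a half-circle
# about the tendon axis).

#' Phantom specification
#'
#' Parameters of the synthetic fascicle phantom. The defaults emulate the
#' DiceCT regime the package targets: 43.863 µm isotropic voxels, fascicle
#' diameter at the upper end of the typical 65--140 µm range, bright fascicle
#' cores over darker perimysial sheaths, and additive Gaussian noise.
#'
#' @param shape Grid dimensions, voxels (length-3 integer).
#' @param spacing Voxel edge length, µm.
#' @param fascicle_radius Fascicle core radius, µm (scalar or per-fascicle).
#' @param layout One of `"parallel"`, `"bipennate"`, `"hemiradial"`.
#' @param pennation Target angle between fascicles and the tendon axis,
#'   degrees in `[0, 90]`.
#' @param n_fascicles Requested fascicle count.
#' @param sheath_thickness Dark sheath shell thickness, µm.
#' @param fg_level,sheath_level,bg_level Grayscale levels of fascicle core,
#'   sheath, and background; must satisfy `fg_level > sheath_level >= bg_level`.
#' @param noise_sd Additive Gaussian noise standard deviation (grayscale).
#' @param taper_fraction Linear radius taper along fascicle length, `[0, 1)`.
#' @param dropout_fraction Fraction of sheath voxels erased to the core
#'   level, `[0, 1)` -- emulates insufficient inter-fascicle contrast.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param strict If `TRUE`, fail when `n_fascicles` cannot be packed without
#'   overlap; if `FALSE`, generate as many as fit and warn.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = 43.863,
                         fascicle_radius = 70,
                         layout = c("bipennate", "parallel", "hemiradial"),
                         pennation = 25,
                         n_fascicles = 40,
                         sheath_thickness = 50,
                         fg_level = 200,
                         sheath_level = 90,
                         bg_level = 50,
                         noise_sd = 20,
                         taper_fraction = 0,
                         dropout_fraction = 0,
                         seed = 1L,
                         strict = FALSE) {
  layout <- match.arg(layout)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) abort("`shape` must be 3 positive integers")
  if (!(fg_level > sheath_level && sheath_level >= bg_level))
    abort("grayscale levels must satisfy fg_level > sheath_level >= bg_level")
  if (any(fascicle_radius < spacing))
    abort("fascicle_radius must be at least one voxel (>= spacing)")
  if (pennation < 0 || pennation > 90) abort("pennation must lie in [0, 90] degrees")
  if (taper_fraction < 0 || taper_fraction >= 1) abort("taper_fraction must lie in [0, 1)")
  if (dropout_fraction < 0 || dropout_fraction >= 1) abort("dropout_fraction must lie in [0, 1)")
  if (n_fascicles < 1) abort("n_fascicles must be >= 1")
  structure(list(shape = shape, spacing = spacing,
                 fascicle_radius = fascicle_radius, layout = layout,
                 pennation = pennation, n_fascicles = as.integer(n_fascicles),
                 sheath_thickness = sheath_thickness,
                 fg_level = fg_level, sheath_level = sheath_level,
                 bg_level = bg_level, noise_sd = noise_sd,
                 taper_fraction = taper_fraction,
                 dropout_fraction = dropout_fraction,
                 seed = as.integer(seed), strict = isTRUE(strict)),
            class = "phantom_spec")
}

#' Generate a fascicle phantom
#'
#' Builds the phantom volume, its muscle label field (union of fascicles
#' dilated by the sheath thickness) and the ground truth. Voxels are
#' classified by center-point inclusion: a voxel belongs to a fascicle core
#' iff its center lies within radius of the centerline segment (flat end
#' caps), and to the sheath iff it lies in the shell out to
#' `radius + sheath_thickness`. Bipennate layouts add a dark tendon plane
#' through the volume center, parallel to the yz-plane.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([mt_volume()]), `label`
#'   ([mt_label()]) and `truth` (ground-truth object; see Details).
#' @details The ground truth is a list of class `mt_ground_truth` with a
#'   per-fascicle tibble (`fascicles`: id, direction, curved length µm,
#'   pennation degrees), centerline polylines in µm world coordinates,
#'   the tendon axis, and the generating geometry (used by
#'   [degrade_phantom()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- place_fascicles(spec)
  if (nrow(geom$seg) < spec$n_fascicles) {
    msg <- sprintf("requested %d fascicles, packed %d without overlap",
                   spec$n_fascicles, nrow(geom$seg))
    if (spec$strict) abort(msg) else warn(msg)
  }
  cls <- classify_voxels(spec, geom)
  vol <- array(spec$bg_level, spec$shape)
  if (spec$layout == "bipennate") {
    # dark internal tendon: plane x = cx, one sheath thickness half-width
    xw <- (seq_len(spec$shape[1]) - 1) * spec$spacing
    cx <- (spec$shape[1] - 1) * spec$spacing / 2
    sel <- abs(xw - cx) <= spec$sheath_thickness
    vol[sel, , ] <- spec$sheath_level
  }
  vol[cls == 1L] <- spec$sheath_level
  vol[cls == 2L] <- spec$fg_level
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$seed, {
      array(rnorm(length(vol), 0, spec$noise_sd), dim(vol))
    })
  }
  label <- label_from_geom(spec, geom)
  truth <- make_ground_truth(spec, geom)
  list(volume = mt_volume(vol, spec$spacing),
       label = mt_label(label, spec$spacing),
       truth = truth)
}

#' Degrade a phantom volume
#'
#' Emulates the failure modes of real stained tissue: `dropout_fraction` of
#' the sheath voxels are erased to the core level (insufficient contrast
#' between adjacent fascicles), and each fascicle's radius is linearly
#' tapered by `taper_fraction` along its length (variable-diameter
#' fascicles), with vacated core voxels set to the sheath level. The ground
#' truth is unchanged.
#'
#' @param vol Phantom volume from [generate_phantom()].
#' @param truth Matching ground truth.
#' @param dropout_fraction,taper_fraction Degradation strengths in `[0, 1)`.
#' @param seed RNG seed for the dropout sample.
#' @return A degraded [mt_volume()].
#' @export
degrade_phantom <- function(vol, truth, dropout_fraction = 0,
                            taper_fraction = 0, seed = 1L) {
  stopifnot(inherits(vol, "mt_volume"), inherits(truth, "mt_ground_truth"))
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    abort("dropout_fraction must lie in [0, 1)")
  if (taper_fraction < 0 || taper_fraction >= 1)
    abort("taper_fraction must lie in [0, 1)")
  spec <- truth$geometry$spec
  geom <- truth$geometry$geom
  out <- vol$data
  if (taper_fraction > 0) {
    cls0 <- classify_voxels(spec, geom)
    cls1 <- classify_voxels(spec, geom, taper_fraction = taper_fraction)
    vacated <- cls0 == 2L & cls1 != 2L
    out[vacated] <- spec$sheath_level
  }
  if (dropout_fraction > 0) {
    cls <- classify_voxels(spec, geom)
    sheath_idx <- which(cls == 1L)
    k <- round(dropout_fraction * length(sheath_idx))
    drop_idx <- with_seed(seed, sample(sheath_idx, k))
    out[drop_idx] <- spec$fg_level
  }
  mt_volume(out, vol$spacing)
}

#' @export
print.mt_ground_truth <- function(x, ...) {
  cat(sprintf("<mt_ground_truth> %d fascicles, tendon axis (%.3g, %.3g, %.3g)\n",
              nrow(x$fascicles), x$tendon_axis[1], x$tendon_axis[2],
              x$tendon_axis[3]))
  invisible(x)
}

#' @export
tidy.mt_ground_truth <- function(x, ...) x$fascicles

# --- internals ---------------------------------------------------------------

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# world-space extent of the grid (voxel centers span [0, (n-1)*s])
grid_extent <- function(spec) (spec$shape - 1) * spec$spacing

# clip the line p0 + t*d to the axis-aligned box [lo, hi]; returns c(t0, t1)
# or NULL when the intersection is empty
clip_line_box <- function(p0, d, lo, hi) {
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-12) {
      if (p0[a] < lo[a] || p0[a] > hi[a]) return(NULL)
    } else {
      ta <- (lo[a] - p0[a]) / d[a]; tb <- (hi[a] - p0[a]) / d[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
    }
  }
  if (t0 >= t1) return(NULL)
  c(t0, t1)
}

# Lay out fascicle centerline segments for the requested layout.
# Returns list(seg = data.frame(x0,y0,z0,dx,dy,dz,len,radius), dirs matrix)
place_fascicles <- function(spec) {
  ext <- grid_extent(spec)
  r <- spec$fascicle_radius
  s <- spec$sheath_thickness
  margin <- max(r) + s
  lo <- rep(margin, 3); hi <- ext - margin
  pen <- spec$pennation * pi / 180
  n <- spec$n_fascicles
  radii <- rep_len(r, n)
  pitch <- 2 * max(r) + 2 * s      # axis-to-axis spacing: sheaths may touch
  segs <- list()

  lattice_lines <- function(d, anchor, lo_box, hi_box, count) {
    # orthonormal frame perpendicular to d
    u <- if (abs(d[3]) < 0.9) normalize(cross3(d, c(0, 0, 1))) else
      normalize(cross3(d, c(0, 1, 0)))
    v <- cross3(d, u)
    span <- ceiling(max(hi_box - lo_box) / pitch) + 1
    ab <- expand.grid(a = -span:span, b = -span:span)
    ab <- ab[order(ab$a^2 + ab$b^2), , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(ab))) {
      p0 <- anchor + ab$a[i] * pitch * u + ab$b[i] * pitch * v
      tt <- clip_line_box(p0, d, lo_box, hi_box)
      if (is.null(tt)) next
      len <- tt[2] - tt[1]
      if (len < 2 * spec$spacing) next
      # snap the start point to the voxel lattice: centerlines pass through
      # voxel centres, making the voxelisation phase deterministic
      start <- round((p0 + tt[1] * d) / spec$spacing) * spec$spacing
      out[[length(out) + 1L]] <- c(start, d, len)
      if (length(out) >= count) break
    }
    out
  }

  if (spec$layout == "parallel") {
    d <- rotz_dir(pen, 0)
    anchor <- (lo + hi) / 2
    segs <- lattice_lines(d, anchor, lo, hi, n)
  } else if (spec$layout == "bipennate") {
    cx <- ext[1] / 2
    tendon_hw <- s
    n_side <- c(ceiling(n / 2), floor(n / 2))
    sides <- c(1, -1)
    for (k in 1:2) {
      sgn <- sides[k]
      d <- normalize(c(sgn * sin(pen), 0, cos(pen)))
      lo_box <- lo; hi_box <- hi
      if (sgn > 0) lo_box[1] <- cx + tendon_hw + margin
      else hi_box[1] <- cx - tendon_hw - margin
      anchor <- (lo_box + hi_box) / 2
      segs <- c(segs, lattice_lines(d, anchor, lo_box, hi_box, n_side[k]))
    }
  } else { # hemiradial
    cx <- ext[1] / 2; cy <- ext[2] / 2
    phis <- seq(0, pi, length.out = n + 1)[seq_len(n)]
    zs <- lo[3] + (hi[3] - lo[3]) *
      ((seq_len(n) * 0.6180339887) %% 1)  # golden-ratio stagger along z
    accepted <- list()
    for (i in seq_len(n)) {
      d <- c(sin(pen) * cos(phis[i]), sin(pen) * sin(phis[i]), cos(pen))
      start <- c(cx, cy, zs[i]) +
        (max(radii) + s + spec$spacing) * c(cos(phis[i]), sin(phis[i]), 0)
      tt <- clip_line_box(start, d, lo, hi)
      if (is.null(tt)) next
      p0 <- start + max(tt[1], 0) * d
      len <- tt[2] - max(tt[1], 0)
      if (len < 2 * spec$spacing) next
      cand <- c(p0, d, len)
      ok <- TRUE
      for (a in accepted) {
        if (segment_distance(cand[1:3], cand[4:6], cand[7],
                             a[1:3], a[4:6], a[7]) < 2 * max(radii) + s) {
          ok <- FALSE; break
        }
      }
      if (ok) accepted[[length(accepted) + 1L]] <- cand
    }
    segs <- accepted
  }

  if (length(segs) == 0L) abort("no fascicle fits the requested phantom geometry")
  m <- do.call(rbind, segs)
  seg <- data.frame(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3],
                    dx = m[, 4], dy = m[, 5], dz = m[, 6], len = m[, 7])
  seg$radius <- rep_len(r, nrow(seg))
  list(seg = seg)
}

normalize <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
rotz_dir <- function(pen, phi) {
  normalize(c(sin(pen) * cos(phi), sin(pen) * sin(phi), cos(pen)))
}

# minimum distance between two finite segments
segment_distance <- function(p1, d1, l1, p2, d2, l2) {
  # sample-based bound is sufficient for packing checks
  t1 <- seq(0, l1, length.out = 24)
  t2 <- seq(0, l2, length.out = 24)
  pts1 <- cbind(p1[1] + t1 * d1[1], p1[2] + t1 * d1[2], p1[3] + t1 * d1[3])
  pts2 <- cbind(p2[1] + t2 * d2[1], p2[2] + t2 * d2[2], p2[3] + t2 * d2[3])
  dd <- outer(rowSums(pts1^2), rowSums(pts2^2), "+") - 2 * pts1 %*% t(pts2)
  sqrt(max(min(dd), 0))
}

# classify voxels: 0 background, 1 sheath, 2 fascicle core.
# Flat end caps; optional linear taper of the core radius along the length.
classify_voxels <- function(spec, geom, taper_fraction = 0) {
  cls <- array(0L, spec$shape)
  sp <- spec$spacing
  s <- spec$sheath_thickness
  for (i in seq_len(nrow(geom$seg))) {
    g <- geom$seg[i, ]
    p0 <- c(g$x0, g$y0, g$z0); d <- c(g$dx, g$dy, g$dz)
    p1 <- p0 + g$len * d
    rmax <- g$radius + s
    lo_i <- pmax(floor(pmin(p0, p1) / sp - rmax / sp) + 1, 1)
    hi_i <- pmin(ceiling(pmax(p0, p1) / sp + rmax / sp) + 1, spec$shape)
    ii <- lo_i[1]:hi_i[1]; jj <- lo_i[2]:hi_i[2]; kk <- lo_i[3]:hi_i[3]
    wx <- (ii - 1) * sp; wy <- (jj - 1) * sp; wz <- (kk - 1) * sp
    nx <- length(ii); ny <- length(jj); nz <- length(kk)
    rx <- array(wx - p0[1], c(nx, ny, nz))
    ry <- aperm(array(wy - p0[2], c(ny, nx, nz)), c(2, 1, 3))
    rz <- aperm(array(wz - p0[3], c(nz, nx, ny)), c(2, 3, 1))
    t <- rx * d[1] + ry * d[2] + rz * d[3]
    rad2 <- rx^2 + ry^2 + rz^2 - t^2
    # flat end caps, half-open at the far end so an aligned cylinder covers
    # exactly len/spacing slices of voxel centres
    inlen <- t >= 0 & t < g$len
    rcore <- g$radius * (1 - taper_fraction * pmin(pmax(t / g$len, 0), 1))
    # relative epsilon keeps exact-boundary lattice points stably inside
    core <- inlen & rad2 <= rcore^2 * (1 + 1e-9)
    sheath <- inlen & !core & rad2 <= rmax^2 * (1 + 1e-9)
    sub <- cls[ii, jj, kk]
    sub[sheath & sub == 0L] <- 1L
    sub[core] <- 2L
    cls[ii, jj, kk] <- sub
  }
  cls
}

# muscle label: union of fascicles dilated by the sheath thickness
# (Minkowski sum with a ball, i.e. rounded caps -- so whole centerlines,
# endpoints included, lie inside the label)
label_from_geom <- function(spec, geom) {
  lab <- array(0, spec$shape)
  sp <- spec$spacing
  s <- spec$sheath_thickness
  for (i in seq_len(nrow(geom$seg))) {
    g <- geom$seg[i, ]
    p0 <- c(g$x0, g$y0, g$z0); d <- c(g$dx, g$dy, g$dz)
    p1 <- p0 + g$len * d
    rmax <- g$radius + s
    lo_i <- pmax(floor(pmin(p0, p1) / sp - rmax / sp) + 1, 1)
    hi_i <- pmin(ceiling(pmax(p0, p1) / sp + rmax / sp) + 1, spec$shape)
    ii <- lo_i[1]:hi_i[1]; jj <- lo_i[2]:hi_i[2]; kk <- lo_i[3]:hi_i[3]
    nx <- length(ii); ny <- length(jj); nz <- length(kk)
    rx <- array((ii - 1) * sp - p0[1], c(nx, ny, nz))
    ry <- aperm(array((jj - 1) * sp - p0[2], c(ny, nx, nz)), c(2, 1, 3))
    rz <- aperm(array((kk - 1) * sp - p0[3], c(nz, nx, ny)), c(2, 3, 1))
    t <- pmin(pmax(rx * d[1] + ry * d[2] + rz * d[3], 0), g$len)
    d2 <- (rx - t * d[1])^2 + (ry - t * d[2])^2 + (rz - t * d[3])^2
    sub <- lab[ii, jj, kk]
    sub[d2 <= rmax^2 * (1 + 1e-9)] <- 1
    lab[ii, jj, kk] <- sub
  }
  lab
}

make_ground_truth <- function(spec, geom) {
  seg <- geom$seg
  dirs <- as.matrix(seg[, c("dx", "dy", "dz")])
  axis <- c(0, 0, 1)
  penn <- acos(pmin(abs(dirs %*% axis), 1)) * 180 / pi
  centerlines <- lapply(seq_len(nrow(seg)), function(i) {
    p0 <- c(seg$x0[i], seg$y0[i], seg$z0[i])
    rbind(p0, p0 + seg$len[i] * dirs[i, ])
  })
  structure(list(
    fascicles = tibble(
      fascicle = seq_len(nrow(seg)),
      dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
      curved_length = seg$len,
      pennation = as.numeric(penn)
    ),
    centerlines = centerlines,
    tendon_axis = axis,
    geometry = list(spec = spec, geom = geom)
  ), class = "mt_ground_truth")
}
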