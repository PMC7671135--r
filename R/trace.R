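# Tract tracing: streamlines through the masked correlation field along the
# orientation field.
#
# Seeds are voxels above the seed-correlation threshold, processed in
# descending correlation order with greedy minimum-distance exclusion
# (a spatial hash at the exclusion radius keeps lookups O(1)). From each
# accepted seed the tract is stepped bidirectionally with an inertia blend
# between the local orientation and the previous step direction; the
# orientation field is axial, so the local vector is sign-flipped into the
# hemisphere of travel before blending.

#' Tracing parameters
#'
#' @param min_seed_correlation Correlation threshold for seeding a tract.
#' @param min_continuation_quality Correlation threshold for continuing a
#'   tract (must not exceed `min_seed_correlation`).
#' @param direction_coefficient Inertia weight in `[0, 1]` on the previous
#'   step direction: `0` follows the orientation field exactly, `1`
#'   continues straight along the seed orientation.
#' @param min_distance Exclusion radius between distinct tracts, µm.
#' @param min_length Minimum curved length of a kept tract, µm.
#' @param max_step_angle Maximum turn per step, degrees.
#' @param step_size Step length, µm; `NULL` means half a voxel.
#' @param max_steps Cap on steps per direction.
#' @return A `trace_params` list.
#' @export
trace_params <- function(min_seed_correlation = 0.2,
                         min_continuation_quality = 0.12,
                         direction_coefficient = 0.5,
                         min_distance = 150,
                         min_length = 1000,
                         max_step_angle = 45,
                         step_size = NULL,
                         max_steps = 5000L) {
  if (!is.finite(min_seed_correlation) || !is.finite(min_continuation_quality))
    abort("correlation thresholds must be finite")
  if (min_continuation_quality > min_seed_correlation)
    abort("min_continuation_quality must be <= min_seed_correlation")
  if (direction_coefficient < 0 || direction_coefficient > 1)
    abort("direction_coefficient must lie in [0, 1]")
  if (!is.null(step_size) && step_size <= 0) abort("step_size must be positive")
  if (min_length < 0) abort("min_length must be >= 0")
  if (min_distance < 0) abort("min_distance must be >= 0")
  if (max_step_angle <= 0 || max_step_angle > 180)
    abort("max_step_angle must lie in (0, 180] degrees")
  structure(list(min_seed_correlation = min_seed_correlation,
                 min_continuation_quality = min_continuation_quality,
                 direction_coefficient = direction_coefficient,
                 min_distance = min_distance, min_length = min_length,
                 max_step_angle = max_step_angle, step_size = step_size,
                 max_steps = as.integer(max_steps)),
            class = "trace_params")
}

#' A single fascicle tract
#'
#' @param points Ordered polyline, n x 3 matrix of µm world coordinates.
#' @return An `mt_tract` with curved length, chord length and the (axial)
#'   mean direction (normalised mean of unit segment vectors).
#' @export
mt_tract <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) abort("a tract needs at least 2 points")
  segs <- diff(points)
  seglen <- sqrt(rowSums(segs^2))
  if (any(seglen == 0)) {
    keep <- c(TRUE, seglen > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 2L) abort("a tract needs at least 2 distinct points")
    segs <- diff(points); seglen <- sqrt(rowSums(segs^2))
  }
  md <- colSums(segs / seglen)
  nmd <- sqrt(sum(md^2))
  md <- if (nmd > 1e-12) md / nmd else c(NA_real_, NA_real_, NA_real_)
  structure(list(points = points,
                 curved_length = sum(seglen),
                 chord_length = sqrt(sum((points[nrow(points), ] - points[1, ])^2)),
                 mean_direction = md),
            class = "mt_tract")
}

#' A set of traced tracts
#'
#' @param tracts List of [mt_tract()].
#' @param params Provenance: the [trace_params()] used.
#' @param source Muscle / volume identifier.
#' @param spacing Voxel spacing, µm.
#' @return An `mt_tract_set`.
#' @export
mt_tract_set <- function(tracts, params = NULL, source = NA_character_,
                         spacing = NA_real_) {
  structure(list(tracts = tracts, params = params, source = source,
                 spacing = spacing),
            class = "mt_tract_set")
}

#' @export
length.mt_tract_set <- function(x) length(x$tracts)

#' @export
print.mt_tract_set <- function(x, ...) {
  cat(sprintf("<mt_tract_set> %d tracts", length(x$tracts)))
  if (length(x$tracts)) {
    cl <- vapply(x$tracts, `[[`, numeric(1), "curved_length")
    cat(sprintf(", curved length %.0f-%.0f um (median %.0f)",
                min(cl), max(cl), median(cl)))
  }
  cat("\n")
  invisible(x)
}

#' Per-tract summary table
#'
#' @param x An `mt_tract_set`.
#' @param ... Unused.
#' @return A tibble with one row per tract: lengths (µm), mean direction
#'   components, and point count.
#' @export
tidy.mt_tract_set <- function(x, ...) {
  if (length(x$tracts) == 0L)
    return(tibble(tract = integer(), curved_length = numeric(),
                  chord_length = numeric(), dir_x = numeric(),
                  dir_y = numeric(), dir_z = numeric(), n_points = integer()))
  tibble(
    tract = seq_along(x$tracts),
    curved_length = vapply(x$tracts, `[[`, numeric(1), "curved_length"),
    chord_length = vapply(x$tracts, `[[`, numeric(1), "chord_length"),
    dir_x = vapply(x$tracts, function(t) t$mean_direction[1], numeric(1)),
    dir_y = vapply(x$tracts, function(t) t$mean_direction[2], numeric(1)),
    dir_z = vapply(x$tracts, function(t) t$mean_direction[3], numeric(1)),
    n_points = vapply(x$tracts, function(t) nrow(t$points), integer(1))
  )
}

#' @export
glance.mt_tract_set <- function(x, ...) {
  td <- tidy(x)
  tibble(n_tracts = nrow(td),
         curved_length_mean = mean(td$curved_length),
         curved_length_median = median(td$curved_length),
         chord_length_mean = mean(td$chord_length))
}

#' Count seed candidates
#'
#' Number of voxels whose correlation passes the seed threshold, before any
#' minimum-distance exclusion. Masked-out voxels (correlation exactly zero)
#' are never candidates.
#'
#' @param fields Masked [mt_fiber_fields()].
#' @param p A [trace_params()] (or a bare threshold).
#' @return Integer count; monotone non-increasing in the threshold.
#' @export
seed_count <- function(fields, p) {
  thr <- if (inherits(p, "trace_params")) p$min_seed_correlation else p
  sum(fields$correlation >= thr & fields$correlation != 0)
}

#' Trace fascicle tracts
#'
#' Stage (3) of the workflow. See the package vignette for the stepping
#' rule: `d_new = normalize((1 - dc) * o(x) + dc * d_prev)` with the axial
#' orientation `o(x)` (nearest voxel) flipped into the hemisphere of
#' `d_prev`, correlation interpolated trilinearly, and termination on low
#' correlation, sharp turns, grid exit, proximity to an existing tract, or
#' the step cap. Tracts shorter than `min_length` are discarded.
#'
#' @param fields Masked [mt_fiber_fields()] (see [apply_mask()]).
#' @param p A [trace_params()].
#' @param source Optional identifier recorded on the result.
#' @return An [mt_tract_set()]; empty when nothing passes the seed threshold.
#' @export
trace_tracts <- function(fields, p, source = NA_character_) {
  stopifnot(inherits(fields, "mt_fiber_fields"), inherits(p, "trace_params"))
  sp <- fields$spacing
  corr <- fields$correlation
  orient <- fields$orientation
  dims <- dim(corr)
  step <- if (is.null(p$step_size)) sp / 2 else p$step_size
  cos_max_turn <- cos(p$max_step_angle * pi / 180)

  cand <- which(corr >= p$min_seed_correlation & corr != 0)
  if (length(cand) == 0L)
    return(mt_tract_set(list(), p, source, sp))
  cand <- cand[order(corr[cand], decreasing = TRUE)]
  seeds <- arrayInd(cand, dims)

  hash <- new_point_hash(max(p$min_distance, sp))
  tracts <- list()

  orient_at <- function(vox) orient[vox[1], vox[2], vox[3], ]

  half_trace <- function(x0, d0) {
    pts <- matrix(NA_real_, p$max_steps, 3)
    n <- 0L
    x <- x0; d_prev <- d0
    reason <- "max_steps"
    repeat {
      if (n >= p$max_steps) break
      vox <- pmin(pmax(round(x / sp) + 1, 1), dims)
      o <- orient_at(vox)
      if (sum(o * d_prev) < 0) o <- -o
      d_new <- (1 - p$direction_coefficient) * o + p$direction_coefficient * d_prev
      nn <- sqrt(sum(d_new^2))
      if (nn < 1e-12) { reason <- "degenerate"; break }
      d_new <- d_new / nn
      if (sum(d_new * d_prev) < cos_max_turn) { reason <- "turn"; break }
      x_new <- x + step * d_new
      fidx <- x_new / sp + 1
      if (any(fidx < 1) || any(fidx > dims)) { reason <- "grid"; break }
      if (trilinear(corr, fidx) < p$min_continuation_quality) {
        reason <- "quality"; break
      }
      if (p$min_distance > 0 &&
          hash_too_close(hash, x_new, p$min_distance)) {
        reason <- "distance"; break
      }
      n <- n + 1L
      pts[n, ] <- x_new
      x <- x_new; d_prev <- d_new
    }
    list(pts = pts[seq_len(n), , drop = FALSE], reason = reason)
  }

  for (s in seq_len(nrow(seeds))) {
    vox <- seeds[s, ]
    x0 <- (vox - 1) * sp
    if (p$min_distance > 0 && hash_too_close(hash, x0, p$min_distance)) next
    d0 <- orient_at(vox)
    fwd <- half_trace(x0, d0)
    bwd <- half_trace(x0, -d0)
    pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))), , drop = FALSE],
                 matrix(x0, 1, 3), fwd$pts)
    if (nrow(pts) < 2L) next
    tr <- mt_tract(pts)
    if (tr$curved_length < p$min_length) next
    attr(tr, "stop_reasons") <- c(backward = bwd$reason, forward = fwd$reason)
    tracts[[length(tracts) + 1L]] <- tr
    if (p$min_distance > 0) hash_insert(hash, tr$points)
  }
  mt_tract_set(tracts, p, source, sp)
}

#' Trilinear interpolation at a fractional voxel index
#'
#' @param arr 3D array.
#' @param fidx Fractional 1-based index, length 3, inside `[1, dim]`.
#' @return Interpolated value.
#' @keywords internal
trilinear <- function(arr, fidx) {
  d <- dim(arr)
  i0 <- pmin(pmax(floor(fidx), 1), d - 1L)
  f <- fidx - i0
  i1 <- i0 + 1L
  c00 <- arr[i0[1], i0[2], i0[3]] * (1 - f[1]) + arr[i1[1], i0[2], i0[3]] * f[1]
  c10 <- arr[i0[1], i1[2], i0[3]] * (1 - f[1]) + arr[i1[1], i1[2], i0[3]] * f[1]
  c01 <- arr[i0[1], i0[2], i1[3]] * (1 - f[1]) + arr[i1[1], i0[2], i1[3]] * f[1]
  c11 <- arr[i0[1], i1[2], i1[3]] * (1 - f[1]) + arr[i1[1], i1[2], i1[3]] * f[1]
  c0 <- c00 * (1 - f[2]) + c10 * f[2]
  c1 <- c01 * (1 - f[2]) + c11 * f[2]
  c0 * (1 - f[3]) + c1 * f[3]
}

# --- spatial hash at the exclusion radius -----------------------------------

new_point_hash <- function(cell) {
  e <- new.env(parent = emptyenv())
  e$cell <- cell
  e$tab <- new.env(parent = emptyenv())
  e
}

hash_key <- function(cix) paste(cix[1], cix[2], cix[3], sep = ",")

hash_insert <- function(h, pts) {
  cix <- floor(pts / h$cell)
  keys <- paste(cix[, 1], cix[, 2], cix[, 3], sep = ",")
  for (u in unique(keys)) {
    cur <- h$tab[[u]]
    add <- pts[keys == u, , drop = FALSE]
    h$tab[[u]] <- if (is.null(cur)) add else rbind(cur, add)
  }
  invisible(h)
}

hash_too_close <- function(h, x, dist) {
  c0 <- floor(x / h$cell)
  d2 <- dist^2
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    pts <- h$tab[[hash_key(c0 + c(dx, dy, dz))]]
    if (is.null(pts)) next
    dd <- (pts[, 1] - x[1])^2 + (pts[, 2] - x[2])^2 + (pts[, 3] - x[3])^2
    if (any(dd < d2)) return(TRUE)
  }
  FALSE
}
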