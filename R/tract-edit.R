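# Automated tract cleanup: the rules stand in for manual deletion of
# implausible tracts (sharp cumulative bends, off-axis travel, out-of-range
# lengths), followed by polyline smoothing.

#' Prune implausible tracts
#'
#' Removes tracts by three independent rules: (a) cumulative turning angle
#' (sum of angles between successive segments) above `max_total_bend`;
#' (b) if `reference_direction` is given, acute angle between the tract's
#' mean direction and the reference above `max_off_axis` (the reproducible
#' form of "travelling perpendicular to the known fascicle direction");
#' (c) curved length outside `length_bounds`. Pruning is idempotent.
#'
#' @param ts An [mt_tract_set()].
#' @param reference_direction Optional unit 3-vector (e.g. the tendon axis).
#' @param max_total_bend Degrees; default 90.
#' @param max_off_axis Degrees; rule (b) is inactive when `NULL`.
#' @param length_bounds Optional `c(min, max)` curved length, µm.
#' @param bend_scale Arc-length resolution (µm) at which rule (a) measures
#'   turning: the polyline is resampled at this interval first, so
#'   sub-scale jitter from fine-stepped tracing does not count as bend
#'   while genuine reversals still do. `NULL` (default) uses the raw
#'   points. [run_pipeline()] passes half the template length.
#' @return The surviving [mt_tract_set()], with a per-rule removal report in
#'   `attr(, "removal_report")` (also via [prune_report()]).
#' @export
prune_tracts <- function(ts, reference_direction = NULL,
                         max_total_bend = 90, max_off_axis = NULL,
                         length_bounds = NULL, bend_scale = NULL) {
  stopifnot(inherits(ts, "mt_tract_set"))
  if (!is.null(length_bounds)) {
    if (length(length_bounds) != 2L || length_bounds[1] > length_bounds[2])
      abort("length_bounds must be c(min, max) with min <= max")
  }
  if (!is.null(reference_direction))
    reference_direction <- reference_direction / sqrt(sum(reference_direction^2))
  n <- length(ts$tracts)
  bad_bend <- bad_axis <- bad_len <- logical(n)
  for (i in seq_len(n)) {
    tr <- ts$tracts[[i]]
    pts_b <- if (is.null(bend_scale)) tr$points else
      resample_polyline(tr$points, bend_scale)
    bad_bend[i] <- total_turning_deg(pts_b) > max_total_bend
    if (!is.null(reference_direction) && !is.null(max_off_axis))
      bad_axis[i] <- axial_angle_deg(tr$mean_direction,
                                     reference_direction) > max_off_axis
    if (!is.null(length_bounds))
      bad_len[i] <- tr$curved_length < length_bounds[1] ||
        tr$curved_length > length_bounds[2]
  }
  keep <- !(bad_bend | bad_axis | bad_len)
  out <- mt_tract_set(ts$tracts[keep], ts$params, ts$source, ts$spacing)
  attr(out, "removal_report") <- tibble(
    rule = c("total_bend", "off_axis", "length_bounds", "total_removed"),
    removed = c(sum(bad_bend), sum(bad_axis), sum(bad_len), sum(!keep))
  )
  out
}

#' @rdname prune_tracts
#' @export
prune_report <- function(ts) attr(ts, "removal_report")

# pick polyline vertices at (at least) `interval` arc-length spacing,
# keeping both endpoints
resample_polyline <- function(points, interval) {
  if (interval <= 0 || nrow(points) < 3L) return(points)
  seglen <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seglen))
  keep <- logical(nrow(points))
  keep[1] <- keep[nrow(points)] <- TRUE
  last <- 0
  for (i in 2:(nrow(points) - 1)) {
    if (s[i] - last >= interval) { keep[i] <- TRUE; last <- s[i] }
  }
  points[keep, , drop = FALSE]
}

# cumulative turning angle of a polyline, degrees
total_turning_deg <- function(points) {
  segs <- diff(points)
  len <- sqrt(rowSums(segs^2))
  segs <- segs[len > 0, , drop = FALSE]
  if (nrow(segs) < 2L) return(0)
  u <- segs / sqrt(rowSums(segs^2))
  d <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  sum(acos(pmin(pmax(d, -1), 1))) * 180 / pi
}

#' Smooth tract polylines
#'
#' Centered weighted moving average of the point coordinates, realised as
#' `(window - 1) / 2` passes of three-point averaging (binomial weights)
#' with the endpoints held fixed. Each pass maps every new segment to a
#' convex combination of consecutive old segments, so the curved length
#' never increases and is monotone non-increasing in the window size;
#' straight tracts are unchanged. Lengths are recomputed.
#'
#' @param ts An [mt_tract_set()].
#' @param window Odd window size in points; 1 is the identity.
#' @return Smoothed [mt_tract_set()].
#' @export
smooth_tracts <- function(ts, window = 5) {
  stopifnot(inherits(ts, "mt_tract_set"))
  if (window < 1 || window %% 2 == 0) abort("window must be odd and >= 1")
  out <- ts
  out$tracts <- lapply(ts$tracts, function(tr)
    mt_tract(smooth_polyline(tr$points, window)))
  attr(out, "removal_report") <- attr(ts, "removal_report")
  out
}

smooth_polyline <- function(points, window) {
  if (window == 1L) return(points)
  n <- nrow(points)
  if (n < 3L) return(points)
  passes <- (window - 1L) %/% 2L
  out <- points
  for (k in seq_len(passes)) {
    mid <- (out[1:(n - 2), , drop = FALSE] + out[2:(n - 1), , drop = FALSE] +
              out[3:n, , drop = FALSE]) / 3
    out[2:(n - 1), ] <- mid
  }
  out
}
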