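# Muscle architecture quantification: pennation angle theta (acute angle
# between a tract and the tendon-aligned axis), fascicle lengths, volume,
# mass, and physiological cross-sectional area
# PCSA = V (cm^3) * cos(theta) / L (cm).

#' Reference frame for pennation measurement
#'
#' The tendon long axis, against which the acute angle theta of each tract
#' is measured. In scans this is established by aligning the internal tendon
#' with the z-axis; phantoms generate along +z by construction.
#'
#' @param tendon_axis 3-vector (normalised internally).
#' @param positive_sense Free-text note on the sign convention.
#' @return An `mt_reference_frame`.
#' @export
reference_frame <- function(tendon_axis = c(0, 0, 1),
                            positive_sense = "angles folded into [0, 90] (axial)") {
  n <- sqrt(sum(tendon_axis^2))
  if (n < 1e-12) abort("tendon_axis must be non-zero")
  structure(list(tendon_axis = tendon_axis / n,
                 positive_sense = positive_sense),
            class = "mt_reference_frame")
}

#' Pennation angle of a tract
#'
#' Acute angle between the tract's mean direction and the tendon axis,
#' folded into `[0, 90]` degrees (tract directions are axial: a tract and
#' its reversal measure the same angle).
#'
#' @param tract An [mt_tract()].
#' @param frame An [mt_reference_frame()][reference_frame].
#' @return Angle in degrees.
#' @export
tract_theta <- function(tract, frame) {
  stopifnot(inherits(tract, "mt_tract"), inherits(frame, "mt_reference_frame"))
  md <- tract$mean_direction
  if (any(!is.finite(md))) abort("tract mean direction is degenerate (zero length)")
  axial_angle_deg(md, frame$tendon_axis)
}

#' Architecture summary of a tract set
#'
#' Unweighted per-tract mean and sample SD of curved length (reported in
#' cm) and of theta (degrees). When a label field is supplied, muscle
#' volume, mass (at `density`) and PCSA are filled in; otherwise they are
#' `NA` and can be completed later.
#'
#' @param ts An [mt_tract_set()] with at least one tract.
#' @param frame An [mt_reference_frame()][reference_frame].
#' @param label Optional [mt_label()] for the muscle volume.
#' @param density Muscle density, g/cm^3 (fixed-tissue value 1.055).
#' @param length_weighted If `TRUE`, weight theta by tract curved length
#'   (off by default: the standard report is the plain per-tract mean).
#' @return An `mt_architecture` object; see [tidy.mt_architecture()].
#' @export
summarize_architecture <- function(ts, frame, label = NULL, density = 1.055,
                                   length_weighted = FALSE) {
  stopifnot(inherits(ts, "mt_tract_set"))
  n <- length(ts$tracts)
  if (n < 1L) abort("cannot summarise an empty tract set")
  len_cm <- vapply(ts$tracts, `[[`, numeric(1), "curved_length") * 1e-4
  th <- vapply(ts$tracts, tract_theta, numeric(1), frame = frame)
  if (length_weighted) {
    w <- len_cm / sum(len_cm)
    theta_mean <- sum(w * th)
  } else {
    theta_mean <- mean(th)
  }
  vol <- if (!is.null(label)) label_volume_cm3(label) else NA_real_
  res <- list(
    n_tracts = n,
    fascicle_length_mean = mean(len_cm),
    fascicle_length_sd = if (n > 1) sd(len_cm) else 0,
    theta_mean = theta_mean,
    theta_sd = if (n > 1) sd(th) else 0,
    volume = vol,
    density = density,
    mass = if (!is.na(vol)) vol * density else NA_real_,
    pcsa = if (!is.na(vol)) pcsa(vol, theta_mean, mean(len_cm)) else NA_real_,
    degenerate_n = n == 1,
    lengths_cm = len_cm, thetas = th
  )
  structure(res, class = "mt_architecture")
}

#' @export
print.mt_architecture <- function(x, ...) {
  cat("<mt_architecture>\n")
  cat(sprintf("  N tracts:        %d%s\n", x$n_tracts,
              if (x$degenerate_n) " (degenerate: SD undefined, reported 0)" else ""))
  cat(sprintf("  Fiber length:    %.3f +/- %.3f cm\n",
              x$fascicle_length_mean, x$fascicle_length_sd))
  cat(sprintf("  Pennation angle: %.2f +/- %.3f deg\n", x$theta_mean, x$theta_sd))
  if (!is.na(x$volume)) {
    cat(sprintf("  Volume:          %.4f cm^3\n", x$volume))
    cat(sprintf("  Mass:            %.4f g (density %.3f g/cm^3)\n",
                x$mass, x$density))
    cat(sprintf("  PCSA:            %.3f cm^2\n", x$pcsa))
  }
  invisible(x)
}

#' One-row architecture table
#'
#' Mirrors the usual method-comparison layout: mass, volume, fiber length
#' mean +/- SD, pennation mean +/- SD, PCSA, N.
#'
#' @param x An `mt_architecture`.
#' @param ... Unused.
#' @export
tidy.mt_architecture <- function(x, ...) {
  tibble(mass_g = x$mass, volume_cm3 = x$volume,
         fiber_length_cm = x$fascicle_length_mean,
         fiber_length_sd_cm = x$fascicle_length_sd,
         pennation_deg = x$theta_mean, pennation_sd_deg = x$theta_sd,
         pcsa_cm2 = x$pcsa, n_tracts = x$n_tracts)
}

#' @export
glance.mt_architecture <- tidy.mt_architecture

#' Muscle volume from a label field
#'
#' Foreground voxel count times voxel volume, converted to cm^3
#' (1 µm^3 = 1e-12 cm^3).
#'
#' @param label An [mt_label()].
#' @return Volume in cm^3.
#' @export
label_volume_cm3 <- function(label) {
  stopifnot(inherits(label, "mt_label"))
  sum(label$data != 0) * label$spacing^3 * 1e-12
}

#' Convert between muscle mass and volume
#'
#' @param value Mass in g or volume in cm^3 (non-negative).
#' @param density Muscle density, g/cm^3; the fixed-muscle literature value
#'   is 1.055.
#' @param direction `"mass_to_volume"` or `"volume_to_mass"`.
#' @return Converted value.
#' @export
#' @examples
#' mass_volume_convert(0.5895, direction = "mass_to_volume")  # 0.5588 cm^3
mass_volume_convert <- function(value, density = 1.055,
                                direction = c("mass_to_volume", "volume_to_mass")) {
  direction <- match.arg(direction)
  if (density <= 0) abort("density must be positive")
  if (any(value < 0)) abort("value must be non-negative")
  if (direction == "mass_to_volume") value / density else value * density
}

#' Physiological cross-sectional area
#'
#' `PCSA = V * cos(theta) / L`, with V in cm^3, theta the mean pennation
#' angle in degrees, and L the mean fascicle length in cm. Proportional to
#' the muscle's maximum isometric force.
#'
#' @param volume Muscle volume, cm^3.
#' @param theta_mean Mean pennation angle, degrees.
#' @param fascicle_length_mean Mean fascicle length, cm (positive).
#' @return PCSA in cm^2.
#' @export
#' @examples
#' pcsa(0.690, 23.53, 1.030)   # 0.614 cm^2
pcsa <- function(volume, theta_mean, fascicle_length_mean) {
  if (any(fascicle_length_mean <= 0)) abort("fascicle length must be positive")
  volume * cos(theta_mean * pi / 180) / fascicle_length_mean
}

#' Orientation distribution about the tendon axis
#'
#' Summarises the radial arrangement of tracts around the tendon axis: an
#' azimuth histogram and the 2x2 second-moment (tensor) matrix of the
#' transverse components of the (hemisphere-aligned) mean directions. For a
#' z-aligned tendon this is the XY tensor; its eigenvectors give the
#' dominant transverse spread directions and its trace is at most 1.
#'
#' @param ts An [mt_tract_set()] with at least one tract.
#' @param frame An [mt_reference_frame()][reference_frame].
#' @param bin_width Azimuth bin width, degrees (must divide 360).
#' @return A list of class `mt_orientation_summary`: `histogram` (tibble of
#'   bin start/end/count), `second_moment` (2x2 matrix), `basis` (the two
#'   transverse unit vectors), `azimuth_deg` (per tract).
#' @export
orientation_summary <- function(ts, frame, bin_width = 10) {
  stopifnot(inherits(ts, "mt_tract_set"))
  if (length(ts$tracts) == 0L) abort("empty tract set")
  if (360 %% bin_width != 0) abort("bin_width must divide 360")
  ax <- frame$tendon_axis
  e1 <- if (abs(ax[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- e1 - sum(e1 * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(ax, e1)
  dirs <- t(vapply(ts$tracts, `[[`, numeric(3), "mean_direction"))
  flip <- as.numeric(dirs %*% ax) < 0
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  tx <- as.numeric(dirs %*% e1)
  ty <- as.numeric(dirs %*% e2)
  az <- (atan2(ty, tx) * 180 / pi) %% 360
  trans_mag <- sqrt(tx^2 + ty^2)
  az[trans_mag < 1e-9] <- NA_real_   # axis-parallel: azimuth undefined
  breaks <- seq(0, 360, by = bin_width)
  counts <- table(cut(az[!is.na(az)], breaks, right = FALSE,
                      include.lowest = TRUE))
  m <- crossprod(cbind(tx, ty)) / nrow(dirs)
  dimnames(m) <- NULL
  structure(list(
    histogram = tibble(azimuth_from = head(breaks, -1),
                       azimuth_to = breaks[-1],
                       count = as.integer(counts)),
    second_moment = m,
    basis = rbind(e1 = e1, e2 = e2),
    azimuth_deg = az
  ), class = "mt_orientation_summary")
}

#' @export
print.mt_orientation_summary <- function(x, ...) {
  cat("<mt_orientation_summary>\n  second-moment matrix:\n")
  print(round(x$second_moment, 4))
  invisible(x)
}
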