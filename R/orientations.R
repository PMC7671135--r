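# Axial orientation sampling on the hemisphere.
#
# Orientations are axial (v and -v are the same fiber direction), so sampling
# the upper hemisphere suffices. Spherical Fibonacci points give a
# deterministic, near-uniform covering without pole clustering; the count is
# grown until the covering radius (checked against a fine reference set under
# the axial metric) is within the requested angular step.

#' Sample axial orientations on the hemisphere
#'
#' Returns a deterministic set of unit vectors covering the upper hemisphere
#' such that every axial direction lies within `angular_sampling` degrees of
#' some sample. The `+z` pole is always included; no two samples are
#' antipodal.
#'
#' @param angular_sampling Orientation grid step, degrees in `(0, 90]`.
#' @return Numeric matrix (n x 3) of unit vectors, first row `(0, 0, 1)`.
#' @export
#' @examples
#' dirs <- sample_orientations(30)
#' range(sqrt(rowSums(dirs^2)))
sample_orientations <- function(angular_sampling) {
  if (!is.numeric(angular_sampling) || length(angular_sampling) != 1L ||
      angular_sampling <= 0 || angular_sampling > 90)
    abort("angular_sampling must be a single value in (0, 90] degrees")
  key <- sprintf("%.10g", angular_sampling)
  cached <- orientation_cache[[key]]
  if (!is.null(cached)) return(cached)
  step <- angular_sampling * pi / 180
  n <- max(4L, ceiling(2.2 / (1 - cos(step))))
  repeat {
    pts <- fibonacci_hemisphere(n)
    pts[1, ] <- c(0, 0, 1)
    if (covering_radius_deg(pts) <= angular_sampling) break
    n <- ceiling(n * 1.25)
  }
  orientation_cache[[key]] <- pts
  pts
}

orientation_cache <- new.env(parent = emptyenv())

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (i + 0.5) / n            # strictly positive: no antipodal pairs
  phi <- i * pi * (3 - sqrt(5))     # golden angle
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# worst-case axial angle from any hemisphere direction to its nearest sample,
# estimated against a fine deterministic reference set (chunked for memory)
covering_radius_deg <- function(pts) {
  m <- max(4000L, 20L * nrow(pts))
  ref <- fibonacci_hemisphere(m)
  worst <- 0
  for (start in seq(1L, m, by = 4000L)) {
    idx <- start:min(start + 3999L, m)
    dots <- abs(ref[idx, , drop = FALSE] %*% t(pts))
    best <- pmin(apply(dots, 1, max), 1)
    worst <- max(worst, max(acos(best)))
  }
  worst * 180 / pi
}

# axial angle in degrees between unit vectors (rows of a vs vector or rows of b)
axial_angle_deg <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(rep(b, nrow(a)), ncol = 3, byrow = TRUE)
  d <- pmin(abs(rowSums(a * b)), 1)
  acos(d) * 180 / pi
}
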