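# ggplot2 views of the result types.

#' Plot a tract set
#'
#' 2D projection of the tract polylines, coloured by pennation angle theta
#' against the given reference frame (the standard lateral-view rendering
#' of a fascicle model).
#'
#' @param object An [mt_tract_set()].
#' @param frame An [mt_reference_frame()][reference_frame].
#' @param axes Which world axes to project onto, e.g. `c("x", "z")`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_tract_set <- function(object, frame = reference_frame(),
                                  axes = c("x", "z"), ...) {
  ax_idx <- match(axes, c("x", "y", "z"))
  if (any(is.na(ax_idx)) || length(ax_idx) != 2L)
    abort("axes must be two of 'x', 'y', 'z'")
  if (length(object$tracts) == 0L) abort("empty tract set")
  dfs <- lapply(seq_along(object$tracts), function(i) {
    tr <- object$tracts[[i]]
    data.frame(tract = i, h = tr$points[, ax_idx[1]], v = tr$points[, ax_idx[2]],
               theta = tract_theta(tr, frame))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                   group = .data$tract,
                                   colour = .data$theta)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 90),
                                    name = expression(theta * " (deg)")) +
    ggplot2::labs(x = sprintf("%s (um)", axes[1]),
                  y = sprintf("%s (um)", axes[2])) +
    ggplot2::theme_minimal()
}

#' Plot an orientation summary
#'
#' Azimuth histogram of tract directions about the tendon axis.
#'
#' @param object An `mt_orientation_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_orientation_summary <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$azimuth_from + .data$azimuth_to) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$azimuth_to[1] - h$azimuth_from[1],
                      fill = "steelblue") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::labs(x = "azimuth about tendon axis (deg)", y = "tracts") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Median and IQR of theta and curved length per run, faceted by swept
#' parameter, with the baseline medians as reference lines.
#'
#' @param table Output of [run_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(table) {
  base <- table[table$parameter == "baseline", ][1, ]
  df <- table[table$parameter != "baseline" & is.na(table$error), ]
  long <- rbind(
    data.frame(parameter = df$parameter, value = df$value,
               metric = "theta (deg)", med = df$theta_median,
               q1 = df$theta_q1, q3 = df$theta_q3,
               baseline = base$theta_median),
    data.frame(parameter = df$parameter, value = df$value,
               metric = "curved length (um)", med = df$length_median,
               q1 = df$length_q1, q3 = df$length_q3,
               baseline = base$length_median)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$med)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                             size = 0.3) +
    ggplot2::facet_grid(metric ~ parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "median (IQR)") +
    ggplot2::theme_bw()
}
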