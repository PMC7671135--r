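# One-factor-at-a-time (OAT) sensitivity sweep: 12 sweepable parameters
# (4 template, erosion depth, 7 tracing), each altered to four values
# around the baseline while all others are held fixed, plus the baseline
# run itself -- the 12 x 4 + 1 = 49-run design.

sweepable_params <- c(
  "outer_cylinder_radius", "cylinder_length", "angular_sampling",
  "mask_cylinder_radius", "erosion_iterations",
  "min_seed_correlation", "min_continuation_quality",
  "direction_coefficient", "min_distance", "min_length",
  "max_step_angle", "step_size"
)

#' Build an OAT sweep plan
#'
#' The default per-parameter grid is the baseline value scaled by
#' `1 +/- factors` (so `factors = c(0.25, 0.75)` spans reasonable to
#' unrealistic values); supply `grid` to override any parameter's value
#' list. Angular sampling is clamped to (0, 90], the direction coefficient
#' to [0, 1], and erosion iterations are rounded to integers.
#'
#' @param baseline Named list with the full parameter bundle: every name in
#'   `myotract:::sweepable_params` (step_size may be `NULL` for the
#'   half-voxel default, in which case supply a numeric baseline to sweep).
#' @param grid Optional named list of per-parameter value vectors.
#' @param factors Scale offsets for the default grid.
#' @return A `sweep_plan`: the baseline and a `runs` tibble (one baseline
#'   row plus one row per parameter x value).
#' @export
sweep_plan <- function(baseline, grid = NULL, factors = c(0.25, 0.75)) {
  missing <- setdiff(sweepable_params, names(baseline))
  if (length(missing))
    abort(paste("baseline is missing parameters:", paste(missing, collapse = ", ")))
  rows <- list(tibble(run = 1L, parameter = "baseline", value = NA_real_))
  rid <- 1L
  for (par in sweepable_params) {
    b <- baseline[[par]]
    vals <- if (!is.null(grid[[par]])) grid[[par]] else default_grid(par, b, factors)
    vals <- unique(vals[vals != b])   # baseline value runs once, as "baseline"
    for (v in vals) {
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- tibble(run = rid, parameter = par, value = v)
    }
  }
  structure(list(baseline = baseline, runs = dplyr::bind_rows(rows)),
            class = "sweep_plan")
}

# default OAT grid: baseline scaled by 1 +/- factors, clamped to each
# parameter's legal range; erosion depth uses additive integer offsets
# (scaling an iteration count is meaningless), bumped upward past any
# clamping collision so the grid always holds four distinct values.
default_grid <- function(par, b, factors) {
  if (par == "erosion_iterations") {
    v <- unique(pmax(b + c(-2L, -1L, 1L, 2L), 0L))
    v <- setdiff(v, b)
    while (length(v) < 4L) v <- c(v, max(v, b) + 1L)
    return(sort(v))
  }
  v <- c(b * (1 - rev(factors)), b * (1 + factors))
  switch(par,
         angular_sampling = pmin(pmax(v, 0.5), 90),
         direction_coefficient = pmin(pmax(v, 0), 1),
         min_seed_correlation = pmin(v, 0.999),
         min_continuation_quality = pmin(v, 0.999),
         v)
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat(sprintf("<sweep_plan> %d runs (%d parameters + baseline)\n",
              nrow(x$runs), length(unique(x$runs$parameter)) - 1L))
  invisible(x)
}

#' Run an OAT sensitivity sweep
#'
#' Executes the pipeline once per plan row. Correlation fields are cached
#' and reused across runs that share template parameters (only runs that
#' alter a template parameter re-correlate; trace-stage runs re-trace on
#' the cached fields). Single-run failures are recorded in the `error`
#' column, not fatal. The result is deterministic and independent of run
#' order.
#'
#' @param vol,label Phantom or scan volume and its muscle label.
#' @param plan A [sweep_plan()].
#' @param frame An [mt_reference_frame()][reference_frame].
#' @param max_total_bend,smooth_window Pipeline post-processing settings.
#' @param verbose Progress messages.
#' @return A tibble, one row per run: parameter, value, tract count,
#'   median / IQR of curved length (µm) and theta (degrees), seed count,
#'   pruning removal count, and error (NA on success).
#' @export
run_sweep <- function(vol, label, plan, frame = reference_frame(),
                      max_total_bend = 90, smooth_window = 5,
                      verbose = FALSE) {
  stopifnot(inherits(plan, "sweep_plan"))
  base <- plan$baseline
  field_cache <- new.env(parent = emptyenv())
  get_fields <- function(tp) {
    key <- sprintf("%.9g|%.9g|%.9g|%.9g", tp$outer_cylinder_radius,
                   tp$cylinder_length, tp$angular_sampling,
                   tp$mask_cylinder_radius)
    f <- field_cache[[key]]
    if (is.null(f)) {
      f <- correlate_volume(vol, tp)
      field_cache[[key]] <- f
    }
    f
  }
  out <- vector("list", nrow(plan$runs))
  for (i in seq_len(nrow(plan$runs))) {
    row <- plan$runs[i, ]
    pars <- base
    if (row$parameter != "baseline") pars[[row$parameter]] <- row$value
    rec <- tryCatch(suppressWarnings({
      tp <- template_params(pars$outer_cylinder_radius, pars$cylinder_length,
                            pars$angular_sampling, pars$mask_cylinder_radius)
      # keep the continuation threshold consistent when the seed threshold
      # is swept below it
      cont <- min(pars$min_continuation_quality, pars$min_seed_correlation)
      tr <- trace_params(pars$min_seed_correlation, cont,
                         pars$direction_coefficient, pars$min_distance,
                         pars$min_length, pars$max_step_angle,
                         pars$step_size)
      res <- run_pipeline(vol, label, tp, tr,
                          erosion_iterations = pars$erosion_iterations,
                          frame = frame, max_total_bend = max_total_bend,
                          smooth_window = smooth_window,
                          fields = get_fields(tp))
      td <- tidy(res$tracts)
      th <- if (nrow(td) > 0)
        vapply(res$tracts$tracts, tract_theta, numeric(1), frame = frame)
      else numeric(0)
      qs <- function(x, p) if (length(x)) as.numeric(quantile(x, p)) else NA_real_
      tibble(run = row$run, parameter = row$parameter, value = row$value,
             n_tracts = nrow(td), n_seeds = res$n_seeds,
             length_median = qs(td$curved_length, 0.5),
             length_q1 = qs(td$curved_length, 0.25),
             length_q3 = qs(td$curved_length, 0.75),
             theta_median = qs(th, 0.5),
             theta_q1 = qs(th, 0.25), theta_q3 = qs(th, 0.75),
             n_removed = res$removal_report$removed[
               res$removal_report$rule == "total_removed"],
             error = NA_character_)
    }), error = function(e) {
      tibble(run = row$run, parameter = row$parameter, value = row$value,
             n_tracts = NA_integer_, n_seeds = NA_integer_,
             length_median = NA_real_, length_q1 = NA_real_,
             length_q3 = NA_real_, theta_median = NA_real_,
             theta_q1 = NA_real_, theta_q3 = NA_real_,
             n_removed = NA_integer_, error = conditionMessage(e))
    })
    if (verbose)
      message(sprintf("run %d/%d: %s = %s", i, nrow(plan$runs),
                      row$parameter, format(row$value)))
    out[[i]] <- rec
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$run)
}

#' Flag runs outside the baseline interquartile range
#'
#' Marks sweep runs whose median curved length or median theta falls
#' outside the baseline run's corresponding IQR. Membership uses closed
#' intervals: a median exactly on Q1 or Q3 is inside.
#'
#' @param table Output of [run_sweep()].
#' @param baseline_row Row of `table` to use as baseline; defaults to the
#'   row with `parameter == "baseline"`.
#' @return `table` with logical columns `length_outlier`, `theta_outlier`,
#'   `outlier`.
#' @export
flag_outliers <- function(table, baseline_row = NULL) {
  if (is.null(baseline_row)) {
    idx <- which(table$parameter == "baseline")
    if (length(idx) == 0L) abort("no baseline row present")
    baseline_row <- table[idx[1], ]
  }
  lo <- function(x, a, b) !is.na(x) & (x < a | x > b)
  table$length_outlier <- lo(table$length_median,
                             baseline_row$length_q1, baseline_row$length_q3)
  table$theta_outlier <- lo(table$theta_median,
                            baseline_row$theta_q1, baseline_row$theta_q3)
  table$outlier <- table$length_outlier | table$theta_outlier
  table
}
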