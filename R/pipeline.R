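# End-to-end pipeline: correlate -> erode + mask -> trace -> prune ->
# smooth -> summarise. Single entry point used by the CLI, the sensitivity
# sweep, and validation.

#' Run the full tracking pipeline
#'
#' @param vol An [mt_volume()].
#' @param label An [mt_label()] on the same grid.
#' @param template A [template_params()].
#' @param trace A [trace_params()].
#' @param erosion_iterations Label erosion passes before masking.
#' @param frame An [mt_reference_frame()][reference_frame].
#' @param max_total_bend,max_off_axis,length_bounds Pruning rules, see
#'   [prune_tracts()].
#' @param smooth_window Smoothing window (odd); 1 disables smoothing.
#' @param density Muscle density, g/cm^3.
#' @param fields Optional precomputed (unmasked) [mt_fiber_fields()] to
#'   reuse across runs sharing template parameters.
#' @param keep_fields Return the fields in the result (memory).
#' @param verbose Progress messages.
#' @return A list: `tracts` (pruned + smoothed [mt_tract_set()]),
#'   `summary` ([summarize_architecture()] result or `NULL` if no tract
#'   survived), `n_seeds`, `removal_report`, and optionally `fields`.
#' @export
run_pipeline <- function(vol, label, template, trace, erosion_iterations = 1,
                         frame = reference_frame(),
                         max_total_bend = 90, max_off_axis = NULL,
                         length_bounds = NULL, smooth_window = 5,
                         density = 1.055, fields = NULL,
                         keep_fields = FALSE, verbose = FALSE) {
  stopifnot(inherits(vol, "mt_volume"), inherits(label, "mt_label"))
  if (!same_grid(vol, label)) abort("volume and label grids differ")
  if (is.null(fields)) fields <- correlate_volume(vol, template, verbose = verbose)
  eroded <- erode_label(label, erosion_iterations)
  masked <- apply_mask(fields, eroded)
  nseeds <- seed_count(masked, trace)
  ts <- trace_tracts(masked, trace)
  pruned <- prune_tracts(ts, reference_direction = frame$tendon_axis,
                         max_total_bend = max_total_bend,
                         max_off_axis = max_off_axis,
                         length_bounds = length_bounds,
                         bend_scale = template$cylinder_length / 2)
  rep_ <- prune_report(pruned)
  if (smooth_window > 1 && length(pruned$tracts) > 0)
    pruned <- smooth_tracts(pruned, smooth_window)
  summ <- if (length(pruned$tracts) > 0)
    summarize_architecture(pruned, frame, label = label, density = density)
  else NULL
  out <- list(tracts = pruned, summary = summ, n_seeds = nseeds,
              removal_report = rep_)
  if (keep_fields) out$fields <- fields
  out
}
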