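#' Run the full dispersion-measurement pipeline on one recording
#'
#' Convenience wrapper chaining the stages applied to every subject/task:
#' exclusion masking ([apply_exclusion_masks()]), cloud segmentation
#' ([segment_cloud()]), metric extent extraction ([extract_extents()]),
#' task-end time alignment ([align_to_task_end()]), view merging
#' ([merge_views()]) and temporal smoothing ([smooth_extents()]).
#'
#' @param side,top [frame_sequence()] objects for the C1 side and C3 top
#'   views; either may be `NULL` if that view was excluded.
#' @param cal_side,cal_top Matching [view_calibration()] objects.
#' @param masks List of [exclusion_mask()] objects (any views mixed; each is
#'   applied to its own view).
#' @param threshold,min_component_area_px Passed to [segment_cloud()].
#' @param window,knot_stride Passed to [smooth_extents()].
#' @param smooth Set `FALSE` to return the raw merged extents.
#' @return A smoothed, task-end-aligned `extent_series`.
#' @export
track_dispersion <- function(side = NULL, top = NULL,
                             cal_side = NULL, cal_top = NULL,
                             masks = list(),
                             threshold = "otsu", min_component_area_px = 20L,
                             window = 30L, knot_stride = 5L,
                             smooth = TRUE) {
  if (is.null(side) && is.null(top))
    stop("at least one view is required")
  run_view <- function(seq, cal) {
    if (is.null(seq)) return(NULL)
    if (is.null(cal)) stop("missing calibration for view ", seq$view_id)
    vm <- Filter(function(m) m$view_id == seq$view_id, masks)
    seq <- apply_exclusion_masks(seq, vm)
    cm <- segment_cloud(seq, threshold = threshold,
                        min_component_area_px = min_component_area_px)
    align_to_task_end(extract_extents(cm, cal))
  }
  merged <- merge_views(run_view(side, cal_side), run_view(top, cal_top))
  if (smooth) smooth_extents(merged, window = window,
                             knot_stride = knot_stride)
  else merged
}
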