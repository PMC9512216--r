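#' Construct a view calibration
#'
#' Maps pixel coordinates of one camera view into metric directional
#' distances from the mouth.  The axis convention is fixed by the view id:
#' for `"C1_side"` image columns carry the frontal x-direction (increasing
#' column = forward) and rows carry the vertical z-direction (decreasing row
#' = up); for `"C3_top"` columns carry x and rows carry the lateral
#' y-direction, symmetric about the origin row.
#'
#' @param view_id `"C1_side"` or `"C3_top"`.
#' @param metres_per_pixel_h Metres per pixel along image columns (> 0).
#' @param metres_per_pixel_v Metres per pixel along image rows (> 0).
#' @param origin_px Mouth position as `c(row, col)`, 0-based.
#' @return A `view_calibration` object.
#' @export
view_calibration <- function(view_id = c("C1_side", "C3_top"),
                             metres_per_pixel_h, metres_per_pixel_v,
                             origin_px) {
  view_id <- match.arg(view_id)
  if (metres_per_pixel_h <= 0 || metres_per_pixel_v <= 0)
    stop("metres-per-pixel factors must be positive")
  if (length(origin_px) != 2L || any(origin_px < 0))
    stop("origin_px must be c(row, col), 0-based, inside the frame")
  structure(
    list(view_id = view_id,
         metres_per_pixel_h = metres_per_pixel_h,
         metres_per_pixel_v = metres_per_pixel_v,
         origin_px = as.numeric(origin_px)),
    class = "view_calibration"
  )
}

#' @export
print.view_calibration <- function(x, ...) {
  cat(sprintf(
    "<view_calibration> %s: %.5g m/px (h), %.5g m/px (v), mouth at row %g, col %g\n",
    x$view_id, x$metres_per_pixel_h, x$metres_per_pixel_v,
    x$origin_px[1], x$origin_px[2]))
  invisible(x)
}

#' Calibrate a view from metric scale bars
#'
#' Each scale bar is a physical rod of known length visible in the image;
#' its metres-per-pixel ratio is `known_length_m` divided by the pixel
#' distance between its endpoints.  Bars aligned within `angle_tol_deg` of
#' the horizontal image axis calibrate the column axis, bars within the
#' tolerance of vertical calibrate the row axis; ratios are averaged per
#' axis.  Both axes must be covered.
#'
#' @param scale_bars List of bars, each a list with `p1`, `p2` (pixel
#'   endpoints `c(x, y)`, 0-based) and `length_m` (known metric length).
#' @param view_id `"C1_side"` or `"C3_top"`.
#' @param origin_px Mouth position `c(row, col)`, 0-based.
#' @param angle_tol_deg Maximum deviation from an image axis, degrees.
#' @return A [view_calibration()].
#' @export
calibrate_view <- function(scale_bars, view_id = c("C1_side", "C3_top"),
                           origin_px, angle_tol_deg = 10) {
  view_id <- match.arg(view_id)
  h_ratios <- numeric(0)
  v_ratios <- numeric(0)
  for (bar in scale_bars) {
    dx <- bar$p2[1] - bar$p1[1]
    dy <- bar$p2[2] - bar$p1[2]
    len_px <- sqrt(dx^2 + dy^2)
    if (len_px == 0) stop("scale bar endpoints coincide (zero pixel length)")
    if (bar$length_m <= 0) stop("scale bar length must be positive")
    angle <- atan2(abs(dy), abs(dx)) * 180 / pi  # 0 = horizontal, 90 = vertical
    if (angle <= angle_tol_deg) {
      h_ratios <- c(h_ratios, bar$length_m / len_px)
    } else if (angle >= 90 - angle_tol_deg) {
      v_ratios <- c(v_ratios, bar$length_m / len_px)
    }
    # oblique bars are ignored
  }
  if (length(h_ratios) == 0L)
    stop("no scale bar usable for the horizontal image axis of ", view_id)
  if (length(v_ratios) == 0L)
    stop("no scale bar usable for the vertical image axis of ", view_id)
  view_calibration(view_id = view_id,
                   metres_per_pixel_h = mean(h_ratios),
                   metres_per_pixel_v = mean(v_ratios),
                   origin_px = origin_px)
}

empty_extent_series <- function(n, fps, subject_id, task_id, task_end_frame,
                                directions) {
  df <- data.frame(
    time_s = (seq_len(n) - 1L) / fps,
    x_front = NA_real_, y_diameter = NA_real_,
    z_up = NA_real_, z_down = NA_real_
  )
  df[directions] <- 0
  structure(df, class = c("extent_series", "data.frame"),
            fps = fps, subject_id = subject_id, task_id = task_id,
            task_end_frame = task_end_frame, directions = directions)
}

#' Directional cloud extents from a segmented view
#'
#' Converts per-frame binary cloud masks into metric maximum extents from
#' the mouth origin.  A side view yields `x_front` (largest forward column
#' distance; pixels behind the mouth are ignored, so the value is clamped at
#' 0), `z_up` and `z_down` (largest distances above/below the origin row).
#' A top view yields `y_diameter`, the full lateral span
#' `(max row - min row + 1) * m/px`, plus a QC copy of the frontal extent in
#' attribute `x_front_qc` (the side view is authoritative for x).  Empty
#' masks give extent 0.  Directions a view cannot see are `NA`.
#'
#' The returned time axis is the raw frame clock `k / fps`; apply
#' [align_to_task_end()] to move time zero to the end of the task.
#'
#' @param masks A `cloud_mask` from [segment_cloud()].
#' @param cal A [view_calibration()] with the same `view_id`.
#' @return An `extent_series` data frame with columns `time_s`, `x_front`,
#'   `y_diameter`, `z_up`, `z_down` (metres) and metadata attributes.
#' @export
extract_extents <- function(masks, cal) {
  if (!inherits(masks, "cloud_mask")) stop("masks must be a cloud_mask")
  if (!inherits(cal, "view_calibration")) stop("cal must be a view_calibration")
  if (masks$view_id != cal$view_id)
    stop(sprintf("mask view_id %s does not match calibration view_id %s",
                 masks$view_id, cal$view_id))
  d <- dim(masks$masks)
  n <- d[3]
  orow <- cal$origin_px[1]
  ocol <- cal$origin_px[2]
  mh <- cal$metres_per_pixel_h
  mv <- cal$metres_per_pixel_v
  directions <- if (cal$view_id == "C1_side") c("x_front", "z_up", "z_down")
                else "y_diameter"
  out <- empty_extent_series(n, masks$fps, masks$subject_id, masks$task_id,
                             masks$task_end_frame, directions)
  x_qc <- if (cal$view_id == "C3_top") numeric(n) else NULL
  for (f in seq_len(n)) {
    idx <- which(masks$masks[, , f], arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    r0 <- idx[, 1L] - 1  # 0-based pixel coordinates
    c0 <- idx[, 2L] - 1
    if (cal$view_id == "C1_side") {
      out$x_front[f] <- max(0, max(c0 - ocol)) * mh
      out$z_up[f] <- max(0, max(orow - r0)) * mv
      out$z_down[f] <- max(0, max(r0 - orow)) * mv
    } else {
      out$y_diameter[f] <- (max(r0) - min(r0) + 1) * mv
      x_qc[f] <- max(0, max(c0 - ocol)) * mh
    }
  }
  if (!is.null(x_qc)) attr(out, "x_front_qc") <- x_qc
  out
}

#' Re-reference the time axis to the end of the task
#'
#' Sets `time_s[k] = (k - task_end_frame) / fps`, so the start of the task
#' has negative times and frame `task_end_frame` sits at t = 0 (the instant
#' phonation or playing stopped).  Values are unchanged; the operation is
#' idempotent for a fixed `task_end_frame`.
#'
#' @param series An `extent_series`.
#' @param task_end_frame 0-based frame index of the task end; defaults to
#'   the value carried by the series.
#' @return The series with the shifted time axis.
#' @export
align_to_task_end <- function(series, task_end_frame = NULL) {
  if (!inherits(series, "extent_series")) stop("series must be an extent_series")
  fps <- attr(series, "fps")
  n <- nrow(series)
  if (is.null(task_end_frame)) task_end_frame <- attr(series, "task_end_frame")
  task_end_frame <- as.integer(task_end_frame)
  if (is.na(task_end_frame) || task_end_frame < 0L || task_end_frame >= n)
    stop("task_end_frame must be in [0, ", n - 1L, "]")
  series$time_s <- (seq_len(n) - 1L - task_end_frame) / fps
  attr(series, "task_end_frame") <- task_end_frame
  attr(series, "aligned") <- TRUE
  series
}

#' Merge side-view and top-view extent series
#'
#' The side view (C1) is authoritative for `x_front`, `z_up` and `z_down`;
#' the top view (C3) contributes `y_diameter`.  The result covers the
#' intersection of the two time ranges.  Either view may be `NULL` (a
#' recording excluded from analysis, as happened to the front view in the
#' studio): the merged series then simply lacks that view's directions.
#'
#' @param side `extent_series` from the C1 side view, or `NULL`.
#' @param top `extent_series` from the C3 top view, or `NULL`.
#' @return A merged `extent_series`.
#' @export
merge_views <- function(side = NULL, top = NULL) {
  if (is.null(side) && is.null(top)) stop("at least one view is required")
  if (is.null(side)) return(top)
  if (is.null(top)) return(side)
  fps_s <- attr(side, "fps")
  fps_t <- attr(top, "fps")
  if (!isTRUE(all.equal(fps_s, fps_t)))
    stop(sprintf("fps mismatch between views: %g vs %g", fps_s, fps_t))
  half <- 0.5 / fps_s
  common <- c(max(min(side$time_s), min(top$time_s)),
              min(max(side$time_s), max(top$time_s)))
  if (common[1] > common[2] + half) stop("views share no overlapping time range")
  keep_s <- side$time_s >= common[1] - half / 10 & side$time_s <= common[2] + half / 10
  s <- side[keep_s, , drop = FALSE]
  # match top samples to the side clock (frames are synchronized)
  ti <- round((s$time_s - top$time_s[1]) * fps_s) + 1L
  if (any(ti < 1L | ti > nrow(top)))
    stop("views share no overlapping time range")
  s$y_diameter <- top$y_diameter[ti]
  dirs <- union(attr(side, "directions"), attr(top, "directions"))
  structure(as.data.frame(s),
            class = c("extent_series", "data.frame"),
            fps = fps_s,
            subject_id = attr(side, "subject_id"),
            task_id = attr(side, "task_id"),
            task_end_frame = attr(side, "task_end_frame"),
            directions = dirs,
            aligned = isTRUE(attr(side, "aligned")),
            x_front_qc = attr(top, "x_front_qc"))
}

#' @export
print.extent_series <- function(x, ...) {
  cat(sprintf(
    "<extent_series> subject %s, task %s: %d samples at %g fps, t in [%.2f, %.2f] s; directions: %s\n",
    attr(x, "subject_id"), attr(x, "task_id"), nrow(x), attr(x, "fps"),
    min(x$time_s), max(x$time_s),
    paste(attr(x, "directions"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}
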