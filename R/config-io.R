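#' Write view calibrations to JSON
#'
#' @param cals A single [view_calibration()] or a list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_view_calibrations <- function(cals, path) {
  if (inherits(cals, "view_calibration")) cals <- list(cals)
  payload <- lapply(cals, function(cal) {
    list(view = cal$view_id,
         metres_per_pixel_h = cal$metres_per_pixel_h,
         metres_per_pixel_v = cal$metres_per_pixel_v,
         origin_px = cal$origin_px)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read view calibrations from JSON
#'
#' @param path JSON path written by [write_view_calibrations()].
#' @return Named list of [view_calibration()] objects keyed by view id.
#' @export
read_view_calibrations <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  out <- list()
  for (p in payload) {
    out[[p$view]] <- view_calibration(p$view, p$metres_per_pixel_h,
                                      p$metres_per_pixel_v,
                                      unlist(p$origin_px))
  }
  out
}

#' Write an extent series as tidy CSV
#'
#' Columns: `subject`, `task`, `fps`, `time_s`, `x_front_m`, `y_diameter_m`,
#' `z_up_m`, `z_down_m` (unmeasured directions are empty).
#'
#' @param series An `extent_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_extents <- function(series, path) {
  df <- data.frame(
    subject = attr(series, "subject_id"),
    task = attr(series, "task_id"),
    fps = attr(series, "fps"),
    time_s = series$time_s,
    x_front_m = series$x_front,
    y_diameter_m = series$y_diameter,
    z_up_m = series$z_up,
    z_down_m = series$z_down
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an extent series from tidy CSV
#'
#' @param path CSV path written by [write_extents()].
#' @return An `extent_series`.
#' @export
read_extents <- function(path) {
  df <- read.csv(path)
  out <- data.frame(time_s = df$time_s,
                    x_front = df$x_front_m, y_diameter = df$y_diameter_m,
                    z_up = df$z_up_m, z_down = df$z_down_m)
  dirs <- c("x_front", "y_diameter", "z_up", "z_down")
  dirs <- dirs[!vapply(out[dirs], function(v) all(is.na(v)), logical(1))]
  structure(out, class = c("extent_series", "data.frame"),
            fps = df$fps[1], subject_id = as.character(df$subject[1]),
            task_id = as.character(df$task[1]),
            task_end_frame = if (any(df$time_s == 0)) which(df$time_s == 0) - 1L
                             else NA_integer_,
            directions = dirs, aligned = TRUE)
}
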