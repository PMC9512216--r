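value_at_timepoint <- function(series, dir, tp) {
  i <- which.min(abs(series$time_s - tp))
  fps <- attr(series, "fps")
  if (abs(series$time_s[i] - tp) > 0.5 / fps + 1e-9) {
    stop(sprintf(
      "timepoint %g s is outside the series of subject %s, task %s",
      tp, attr(series, "subject_id"), attr(series, "task_id")))
  }
  series[[dir]][i]
}

#' Cross-subject summary table of dispersion extents
#'
#' For each task, dimension and requested timepoint, computes the median
#' and the maximum across subjects of the per-subject extent at that
#' timepoint (nearest time-grid sample within half a frame; values are
#' frame-based measurements, so no interpolation is done).  The median of
#' an even number of subjects is the mean of the central pair.
#'
#' By convention the published table shape carries the frontal distance and
#' the lateral diameter; vertical (z) statistics are computed the same way
#' but reported separately — request them via `dimensions`.
#'
#' @param series List of (smoothed) `extent_series`, one per subject/task,
#'   each aligned so t = 0 is the task end.
#' @param timepoints_s Timepoints in seconds after task end (default 0, 3,
#'   10).
#' @param dimensions Directions to tabulate (default `x_front` and
#'   `y_diameter`).
#' @return A `summary_table` data frame with columns `task`, `dimension`,
#'   `statistic` (`"median"`/`"maximum"`), `timepoint_s`, `value_m`,
#'   `n_subjects`.
#' @export
summarize_dispersion <- function(series, timepoints_s = c(0, 3, 10),
                                 dimensions = c("x_front", "y_diameter")) {
  if (inherits(series, "extent_series")) series <- list(series)
  if (length(series) == 0L) stop("at least one series is required")
  tasks <- vapply(series, function(s) as.character(attr(s, "task_id")),
                  character(1))
  tasks[is.na(tasks)] <- "unlabelled"
  rows <- list()
  for (task in unique(tasks)) {
    members <- series[tasks == task]
    for (dir in dimensions) {
      ok <- vapply(members, function(s) dir %in% attr(s, "directions"),
                   logical(1))
      if (!any(ok)) next
      for (tp in timepoints_s) {
        vals <- vapply(members[ok], value_at_timepoint, numeric(1),
                       dir = dir, tp = tp)
        rows[[length(rows) + 1L]] <- data.frame(
          task = task, dimension = dir,
          statistic = c("median", "maximum"),
          timepoint_s = tp,
          value_m = c(median(vals), max(vals)),
          n_subjects = sum(ok)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Pointwise median curve across subjects
#'
#' Computes, for every direction and every time sample in the intersection
#' of the input time ranges, the median across subjects — the curve shape
#' used to display dispersion over time.
#'
#' @param series List of `extent_series` sharing the same fps.
#' @return A data frame with `time_s` and one column per direction present
#'   in all inputs.
#' @export
median_curve <- function(series) {
  if (inherits(series, "extent_series")) series <- list(series)
  if (length(series) == 0L) stop("at least one series is required")
  fps <- attr(series[[1]], "fps")
  for (s in series) {
    if (!isTRUE(all.equal(attr(s, "fps"), fps)))
      stop("all series must share the same fps")
  }
  lo <- max(vapply(series, function(s) min(s$time_s), numeric(1)))
  hi <- min(vapply(series, function(s) max(s$time_s), numeric(1)))
  if (lo > hi + 1e-9) stop("series share no overlapping time range")
  tgrid <- series[[1]]$time_s
  tgrid <- tgrid[tgrid >= lo - 1e-9 & tgrid <= hi + 1e-9]
  dirs <- Reduce(intersect, lapply(series, attr, "directions"))
  if (length(dirs) == 0L) stop("series share no measured direction")
  out <- data.frame(time_s = tgrid)
  for (dir in dirs) {
    mat <- vapply(series, function(s) {
      ti <- round((tgrid - s$time_s[1]) * fps) + 1L
      s[[dir]][ti]
    }, numeric(length(tgrid)))
    out[[dir]] <- apply(matrix(mat, nrow = length(tgrid)), 1L, median)
  }
  out
}

#' Classify a value against its reference task (the +/- 0.1 m markup)
#'
#' Published dispersion tables mark each cell relative to a reference task:
#' values at least `tolerance_m` above the reference are flagged `"higher"`
#' (italic in print), values at least `tolerance_m` below are `"lower"`
#' (bold), and values within the open +/- `tolerance_m` band are
#' `"comparable"` (unmarked).  The threshold is inclusive, and both values
#' are first rounded to 0.01 m, the precision at which such tables print.
#'
#' @param value_m Measured value(s), metres (>= 0).
#' @param reference_m Reference-task value(s), metres (>= 0), recycled.
#' @param tolerance_m Comparison tolerance, metres (default 0.1).
#' @return A data frame with columns `mark` (`"higher"`, `"lower"`,
#'   `"comparable"`), `difference_m` (value minus reference, at 0.01 m
#'   precision) and `tolerance_m`.
#' @export
classify_vs_reference <- function(value_m, reference_m, tolerance_m = 0.1) {
  if (length(tolerance_m) != 1L || is.na(tolerance_m) || tolerance_m < 0)
    stop("tolerance_m must be a single non-negative number")
  if (any(value_m < 0) || any(reference_m < 0))
    stop("values and references must be non-negative distances")
  v <- round(value_m, 2)
  r <- round(reference_m, 2)
  d <- round(v - r, 2)
  mark <- ifelse(d >= tolerance_m - 1e-9, "higher",
          ifelse(-d >= tolerance_m - 1e-9, "lower", "comparable"))
  data.frame(mark = mark, difference_m = d, tolerance_m = tolerance_m)
}

#' Default task comparison scheme
#'
#' Playing tasks T2 and T3 are compared to the speaking task T1; the
#' safety-device tasks T4-T6 are compared to unprotected high-octave
#' playing T3.
#'
#' @return Named character vector mapping task to reference task.
#' @export
default_reference_scheme <- function() {
  c(T2 = "T1", T3 = "T1", T4 = "T3", T5 = "T3", T6 = "T3")
}

#' Apply the comparison markup to a whole summary table
#'
#' Joins every cell of a [summarize_dispersion()]-shaped table with the
#' corresponding cell (same dimension, statistic and timepoint) of its
#' reference task and classifies it with [classify_vs_reference()].
#'
#' @param table A `summary_table` data frame (columns `task`, `dimension`,
#'   `statistic`, `timepoint_s`, `value_m`).
#' @param scheme Named character vector task -> reference task.
#' @param tolerance_m Comparison tolerance, metres.
#' @return The table rows for tasks in `scheme`, with added columns
#'   `reference_task`, `reference_m`, `difference_m`, `mark`.
#' @export
mark_dispersion_table <- function(table, scheme = default_reference_scheme(),
                                  tolerance_m = 0.1) {
  keep <- table$task %in% names(scheme)
  out <- table[keep, , drop = FALSE]
  out$reference_task <- unname(scheme[out$task])
  key <- function(task, dim, stat, tp) paste(task, dim, stat, tp, sep = "|")
  ref_idx <- match(
    key(out$reference_task, out$dimension, out$statistic, out$timepoint_s),
    key(table$task, table$dimension, table$statistic, table$timepoint_s))
  if (anyNA(ref_idx))
    stop("reference cell missing for some table rows")
  out$reference_m <- table$value_m[ref_idx]
  cls <- classify_vs_reference(out$value_m, out$reference_m, tolerance_m)
  out$difference_m <- cls$difference_m
  out$mark <- cls$mark
  rownames(out) <- NULL
  out
}

summary_cell <- function(table, cell) {
  idx <- which(table$task == cell$task &
               table$dimension == cell$dimension &
               table$statistic == cell$statistic &
               abs(table$timepoint_s - cell$timepoint_s) < 1e-9)
  if (length(idx) != 1L)
    stop(sprintf("cell not found: %s %s %s %g s",
                 cell$task, cell$dimension, cell$statistic,
                 cell$timepoint_s))
  table$value_m[idx]
}

#' Differences between pairs of summary-table cells
#'
#' Reports `cell_a - cell_b` in metres for each requested pair, at the
#' table's 0.01 m precision.  Each cell is addressed by `task`,
#' `dimension`, `statistic` and `timepoint_s`.
#'
#' @param table A `summary_table` data frame.
#' @param pairs List of pairs; each pair is a list with elements `a` and
#'   `b`, each a list with `task`, `dimension`, `statistic`, `timepoint_s`.
#' @return Data frame describing each pair with its `difference_m`.
#' @export
report_differences <- function(table, pairs) {
  rows <- lapply(pairs, function(pr) {
    va <- summary_cell(table, pr$a)
    vb <- summary_cell(table, pr$b)
    data.frame(
      task_a = pr$a$task, task_b = pr$b$task,
      dimension = pr$a$dimension, statistic = pr$a$statistic,
      timepoint_s = pr$a$timepoint_s,
      value_a_m = va, value_b_m = vb,
      difference_m = round(va - vb, 2)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled reference dispersion table for the soprano recorder study design
#'
#' The published summary table of a five-subject soprano-recorder study:
#' cross-subject median and maximum frontal distance (`x_front`) and
#' lateral diameter (`y_diameter`) at 0, 3 and 10 s after task end, for the
#' six tasks (T1 speaking, T2 low octave, T3 high octave, T4 mask and bell
#' hole tissue, T5 paper towel, T6 suction funnel), together with the
#' printed comparison marks (`"higher"` = italic, `"lower"` = bold,
#' `"comparable"` = unmarked, `"reference"` for the T1 baseline cells).
#' Used to validate the markup classifier and difference reporting.
#'
#' @return A `summary_table` data frame with the additional column
#'   `printed_mark`.
#' @export
recorder_dispersion_table <- function() {
  path <- system.file("extdata", "recorder_dispersion_table.csv",
                      package = "plumetrack", mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("summary_table", "data.frame")
  out
}
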