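#' Moving median filter
#'
#' Centred sliding-window median.  For an even window of length `w` the
#' interior window at index `i` spans offsets `-(w/2 - 1) .. w/2`, and the
#' median of an even number of points is the mean of the two central order
#' statistics.  Near the series boundaries the window shrinks symmetrically
#' to the points available (no padding, so no data are invented beyond the
#' task bounds, and the filter stays centred: endpoints pass through
#' unchanged).  Output length equals input length.  The default window of
#' 30 samples is 1.2 s at 25 fps.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (>= 1).
#' @return Filtered numeric vector of the same length.
#' @export
moving_median <- function(x, window = 30L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  n <- length(x)
  if (n == 0L) return(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i - 1L < half_lo || n - i < half_hi) {
      r <- min(i - 1L, n - i)  # symmetric shrink at the boundaries
      lo <- i - r
      hi <- i + r
    } else {
      lo <- i - half_lo
      hi <- i + half_hi
    }
    out[i] <- median(x[lo:hi])
  }
  out
}

# Natural-ish cubic spline through a subsampled set of knots, evaluated on
# the full grid.  FMM end conditions (cubic fitted through the outermost
# four knots) are used so that data sampled from a single cubic polynomial
# are reproduced exactly.
spline_through_knots <- function(t, y, knot_stride) {
  n <- length(y)
  ks <- unique(c(seq(1L, n, by = knot_stride), n))
  if (length(ks) < 4L)
    stop("too few spline knots (", length(ks),
         "); reduce knot_stride or provide a longer series")
  spline(t[ks], y[ks], xout = t, method = "fmm")$y
}

#' Cubic-spline smoothing of an extent series
#'
#' Fits an interpolating cubic spline through every `knot_stride`-th sample
#' (endpoints always included) and evaluates it on the full time grid,
#' removing residual segmentation outliers that survive the median filter.
#' With `knot_stride = 1` this is the identity on the grid.  Negative spline
#' excursions are clamped to 0 by default, since extents are distances.
#'
#' @param x Numeric vector, or an `extent_series` (each measured direction
#'   is smoothed independently).
#' @param knot_stride Knot subsampling stride in samples (default 5, i.e.
#'   0.2 s at 25 fps).
#' @param clamp_nonnegative Clamp the result at 0.
#' @param time Optional time axis for a numeric `x` (defaults to the sample
#'   index).
#' @return Object of the same type as `x`, smoothed.
#' @export
spline_smooth <- function(x, knot_stride = 5L, clamp_nonnegative = TRUE,
                          time = NULL) {
  knot_stride <- as.integer(knot_stride)
  if (is.na(knot_stride) || knot_stride < 1L) stop("knot_stride must be >= 1")
  if (inherits(x, "extent_series")) {
    for (dir in attr(x, "directions")) {
      x[[dir]] <- spline_smooth(x[[dir]], knot_stride, clamp_nonnegative,
                                time = x$time_s)
    }
    attr(x, "smoothing") <- c(attr(x, "smoothing"),
                              list(knot_stride = knot_stride))
    return(x)
  }
  if (is.null(time)) time <- seq_along(x)
  out <- spline_through_knots(time, x, knot_stride)
  if (clamp_nonnegative) out <- pmax(out, 0)
  out
}

#' Temporal smoothing of a dispersion extent series
#'
#' The standard two-stage filter applied to each directional maximum-extent
#' trace: a moving median (default window 30 samples) removes segmentation
#' spikes, then a cubic-spline interpolation through subsampled knots
#' (default every 5th sample) smooths what remains.
#'
#' @param series An `extent_series` (see [extract_extents()],
#'   [merge_views()]).
#' @param window Moving-median window length in samples.
#' @param knot_stride Spline knot stride in samples.
#' @param clamp_nonnegative Clamp smoothed extents at 0.
#' @return The smoothed `extent_series`, with the filter settings recorded
#'   in attribute `smoothing`.
#' @export
smooth_extents <- function(series, window = 30L, knot_stride = 5L,
                           clamp_nonnegative = TRUE) {
  if (!inherits(series, "extent_series"))
    stop("series must be an extent_series")
  for (dir in attr(series, "directions")) {
    series[[dir]] <- moving_median(series[[dir]], window)
  }
  attr(series, "smoothing") <- list(window = window)
  spline_smooth(series, knot_stride, clamp_nonnegative)
}
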