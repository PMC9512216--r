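#' Otsu threshold of an 8-bit frame
#'
#' Maximizes the between-class variance of the intensity histogram and
#' returns the smallest intensity assigned to the upper class, i.e. the
#' mask condition is `intensity >= otsu_threshold(frame)`.
#'
#' @param frame Integer matrix with values in `[0, 255]`.
#' @return Integer threshold in `[1, 255]`.
#' @export
otsu_threshold <- function(frame) {
  h <- tabulate(as.integer(frame) + 1L, nbins = 256L)
  n <- sum(h)
  p <- h / n
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  # between-class variance for split after level k (k = 0..254)
  w0 <- omega[1:255]
  m0 <- mu[1:255]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b) - 1L  # upper class starts at k + 1
  k + 1L
}

#' Segment the vapor cloud in every frame
#'
#' Global thresholding plus small-component removal: a pixel belongs to the
#' cloud iff its intensity is on the cloud side of the threshold and its
#' 8-connected component has at least `min_component_area_px` pixels.  All
#' surviving components are retained and treated together as one cloud (the
#' vapor escapes through both the labium and the bell hole and merges).
#'
#' With `threshold = "otsu"` the threshold is computed per frame by Otsu's
#' method and clamped to at least `min_threshold` (at most
#' `255 - min_threshold` for dark polarity), which prevents near-uniform
#' background frames from segmenting noise.
#'
#' @param seq A [frame_sequence()], already exclusion-masked.
#' @param threshold Numeric intensity in `[0, 255]`, or `"otsu"`.
#' @param min_component_area_px Minimum 8-connected component area (px).
#' @param polarity `"bright"` (cloud brighter than threshold, the native
#'   white-on-black studio polarity) or `"dark"` (for negative-converted
#'   footage; the mask condition becomes `intensity <= threshold`).
#' @param min_threshold Clamp applied to per-frame Otsu thresholds.
#' @return A `cloud_mask` object: logical `rows x cols x n` array `masks`,
#'   per-frame `threshold_used` and `area_px`, plus the sequence metadata.
#' @export
segment_cloud <- function(seq, threshold = "otsu", min_component_area_px = 20L,
                          polarity = c("bright", "dark"), min_threshold = 50L) {
  polarity <- match.arg(polarity)
  if (!inherits(seq, "frame_sequence"))
    stop("seq must be a frame_sequence")
  fixed <- NULL
  if (is.numeric(threshold)) {
    if (length(threshold) != 1L || is.na(threshold) ||
        threshold < 0 || threshold > 255)
      stop("threshold must be in [0, 255]")
    fixed <- threshold
  } else if (!identical(threshold, "otsu")) {
    stop("threshold must be a number in [0, 255] or \"otsu\"")
  }
  if (min_component_area_px < 0L) stop("min_component_area_px must be >= 0")
  d <- dim(seq$frames)
  masks <- array(FALSE, dim = d)
  thr_used <- numeric(d[3])
  area <- integer(d[3])
  for (f in seq_len(d[3])) {
    fr <- seq$frames[, , f]
    t_f <- if (is.null(fixed)) {
      ot <- otsu_threshold(fr)
      if (polarity == "bright") max(ot, min_threshold)
      else min(ot - 1L, 255L - min_threshold)  # cloud is the lower class
    } else {
      fixed
    }
    bin <- if (polarity == "bright") fr >= t_f else fr <= t_f
    if (any(bin) && min_component_area_px > 1L) {
      lab <- cc_label(bin, 8L)
      sizes <- tabulate(lab[lab > 0L])
      keep <- which(sizes >= min_component_area_px)
      bin <- array(lab %in% keep, dim = d[1:2])
    }
    masks[, , f] <- bin
    thr_used[f] <- t_f
    area[f] <- sum(bin)
  }
  structure(
    list(masks = masks, threshold_used = thr_used, area_px = area,
         min_component_area_px = as.integer(min_component_area_px),
         polarity = polarity,
         fps = seq$fps, view_id = seq$view_id, subject_id = seq$subject_id,
         task_id = seq$task_id, task_end_frame = seq$task_end_frame),
    class = "cloud_mask"
  )
}

#' @export
print.cloud_mask <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf(
    "<cloud_mask> %s: %d frames of %d x %d px, mean cloud area %.1f px\n",
    x$view_id, d[3], d[1], d[2], mean(x$area_px)))
  invisible(x)
}
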