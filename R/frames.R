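#' Construct a frame sequence
#'
#' A `frame_sequence` holds the ordered 8-bit grayscale frames of one camera
#' view for one task, together with the timing and identity metadata needed
#' downstream: frames per second, view id (`"C1_side"` or `"C3_top"`),
#' subject and task labels, and the index of the frame at which the task
#' ended (time zero of the dispersion time axis).
#'
#' @param frames A `rows x cols x n` integer array, or a list of equally
#'   sized integer matrices, with intensities in `[0, 255]`.
#' @param fps Frames per second (> 0); studio recordings here are 25 fps.
#' @param view_id `"C1_side"` (columns carry x-front, rows carry vertical z)
#'   or `"C3_top"` (columns carry x-front, rows carry lateral y).
#' @param subject_id,task_id Optional labels (tasks are `"T1"`..`"T6"`).
#' @param task_end_frame 0-based index of the frame where phonation/playing
#'   stopped; must lie within the sequence.
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, fps, view_id = c("C1_side", "C3_top"),
                           subject_id = NA_character_, task_id = NA_character_,
                           task_end_frame = 0L) {
  view_id <- match.arg(view_id)
  if (is.list(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (ncol(dims) > 1L && any(dims != dims[, 1L]))
      stop("all frames must have identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1L, 1L], dims[2L, 1L], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a rows x cols x n array or list of matrices")
  storage.mode(frames) <- "integer"
  rng <- range(frames)
  if (anyNA(frames) || rng[1] < 0L || rng[2] > 255L)
    stop("frame intensities must be integers in [0, 255]")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number")
  n <- dim(frames)[3]
  task_end_frame <- as.integer(task_end_frame)
  if (task_end_frame < 0L || task_end_frame >= n)
    stop("task_end_frame must be in [0, ", n - 1L, "]")
  structure(
    list(frames = frames, fps = fps, view_id = view_id,
         subject_id = subject_id, task_id = task_id,
         task_end_frame = task_end_frame),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_sequence> %s: %d frames of %d x %d px, %.6g fps (%.2f s), task end at frame %d\n",
    x$view_id, d[3], d[1], d[2], x$fps, d[3] / x$fps, x$task_end_frame))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `frame_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' Duration of a sequence in seconds
#' @param seq A `frame_sequence`.
#' @return Duration `n / fps` in seconds.
#' @export
sequence_duration <- function(seq) n_frames(seq) / seq$fps

# Rec.601 luma, rounded to the nearest integer.
rgb_to_luma <- function(arr) {
  y <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  m <- as.integer(round(y))
  dim(m) <- dim(arr)[1:2]
  m
}

#' Load a directory of image frames as a sequence
#'
#' Reads all PNG/PGM files from `path` in filename-lexicographic order.
#' RGB PNG input is converted to grayscale with the Rec.601 luma weighting
#' (0.299 R + 0.587 G + 0.114 B, rounded).
#'
#' @param path Directory containing the frame images.
#' @param fps Frames per second of the recording.
#' @inheritParams frame_sequence
#' @return A [frame_sequence()].
#' @export
load_frames <- function(path, fps, view_id = c("C1_side", "C3_top"),
                        subject_id = NA_character_, task_id = NA_character_,
                        task_end_frame = 0L) {
  files <- sort(list.files(path, pattern = "\\.(png|pgm)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no PNG or PGM frames found in ", path)
  frames <- vector("list", length(files))
  ref_dim <- NULL
  for (i in seq_along(files)) {
    img <- if (grepl("\\.pgm$", files[i], ignore.case = TRUE)) {
      read_pgm(files[i])
    } else {
      read_png(files[i])
    }
    if (length(dim(img)) == 3L) img <- rgb_to_luma(img)
    if (is.null(ref_dim)) {
      ref_dim <- dim(img)
    } else if (!identical(dim(img), ref_dim)) {
      stop(sprintf("frame %s has dimensions %d x %d, expected %d x %d",
                   basename(files[i]), nrow(img), ncol(img),
                   ref_dim[1], ref_dim[2]))
    }
    frames[[i]] <- img
  }
  frame_sequence(frames, fps = fps, view_id = view_id,
                 subject_id = subject_id, task_id = task_id,
                 task_end_frame = task_end_frame)
}

#' Write a frame sequence as an image stack
#'
#' Files are named `frame_000001.png` (or `.pgm`) onwards so that
#' lexicographic order equals temporal order.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"pgm"`.
#' @param prefix Filename prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_frames <- function(seq, dir, format = c("png", "pgm"),
                         prefix = "frame_") {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(seq)
  files <- file.path(dir, sprintf("%s%06d.%s", prefix, seq_len(n), format))
  writer <- if (format == "png") write_png else write_pgm
  for (i in seq_len(n)) writer(seq$frames[, , i], files[i])
  invisible(files)
}

#' Negative black-and-white conversion
#'
#' Elementwise intensity inversion `i' = 255 - i`, the standard preparation
#' step that renders a white cloud on a dark studio background as a dark
#' cloud on white.  Applying it twice restores the input.  Segmentation in
#' this package operates on either polarity (see [segment_cloud()]).
#'
#' @param x A `frame_sequence` or a single integer frame matrix.
#' @return Object of the same type with inverted intensities.
#' @export
to_negative_bw <- function(x) {
  if (inherits(x, "frame_sequence")) {
    x$frames <- 255L - x$frames
    x
  } else if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    if (anyNA(x) || min(x) < 0L || max(x) > 255L)
      stop("frame intensities must be integers in [0, 255]")
    255L - x
  } else {
    stop("x must be a frame_sequence or an integer matrix")
  }
}
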