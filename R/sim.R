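#' Define a synthetic plume scenario
#'
#' Describes a synthetic two-view recording of a vapor cloud expelled from a
#' fixed mouth origin during a phonation/playing task of
#' `task_duration_s` seconds, followed by `post_task_s` seconds of
#' drift/stagnation.  The ground-truth extent in each physical direction
#' follows a saturating-exponential rise during the task,
#' `d(t) = A * (1 - exp(-(t + task_duration) / tau))` for
#' `t in [-task_duration, 0]` (t = 0 is the task end), continued as
#' `d(0) + drift * t` afterwards — an idealization of clouds that grow
#' while driven by the exhalation jet and then stagnate or drift slowly.
#'
#' The defaults state a world matching the studio experiments this package
#' emulates: 8 s tasks observed for 10 s more at 25 fps, 0.01 m/px
#' calibration, and asymptotes chosen so the frontal extent reaches about
#' 1.06 m and the lateral diameter about 0.57 m at task end.
#'
#' @param task_duration_s Task length in seconds.
#' @param post_task_s Observed time after task end, seconds.
#' @param fps Frames per second.
#' @param frame_size_px Frame size `c(rows, cols)`.
#' @param origin_px Mouth pixel `c(row, col)`, 0-based, both views.
#' @param metres_per_pixel Metres per pixel (both axes, both views).
#' @param expansion_params Named list over directions `x_front`,
#'   `y_diameter`, `z_up`, `z_down`; each a list with `A` (asymptote,
#'   metres), `tau` (time constant, seconds) and `drift` (m/s after task
#'   end).
#' @param noise_sd Additive Gaussian intensity noise SD (8-bit units).
#' @param reflection_artifacts Render a bright floor-reflection patch
#'   (side view) inside a declared `reflection` exclusion polygon.
#' @param body_silhouette Render a bright body silhouette behind the mouth
#'   (both views) inside declared `body` exclusion polygons.
#' @param funnel_release Render a detached stray cloud (as released at a
#'   suction-funnel outlet) inside declared `funnel_release` polygons.
#' @param subject_id,task_id Labels carried through the pipeline.
#' @param seed Integer seed; with the same seed the generated frames are
#'   bit-identical.
#' @return A validated `plume_scenario` object.
#' @export
plume_scenario <- function(task_duration_s = 8,
                           post_task_s = 10,
                           fps = 25,
                           frame_size_px = c(180L, 320L),
                           origin_px = c(90, 60),
                           metres_per_pixel = 0.01,
                           expansion_params = list(
                             x_front    = list(A = 1.08, tau = 2,   drift = 0.010),
                             y_diameter = list(A = 0.58, tau = 2.5, drift = 0),
                             z_up       = list(A = 0.50, tau = 3,   drift = 0.005),
                             z_down     = list(A = 0.30, tau = 3,   drift = 0)
                           ),
                           noise_sd = 5,
                           reflection_artifacts = FALSE,
                           body_silhouette = FALSE,
                           funnel_release = FALSE,
                           subject_id = "S1",
                           task_id = "T3",
                           seed = 1L) {
  sc <- structure(
    list(task_duration_s = task_duration_s, post_task_s = post_task_s,
         fps = fps, frame_size_px = as.integer(frame_size_px),
         origin_px = as.numeric(origin_px),
         metres_per_pixel = metres_per_pixel,
         expansion_params = expansion_params,
         noise_sd = noise_sd,
         background_intensity = 20L, plume_intensity = 230L,
         reflection_artifacts = isTRUE(reflection_artifacts),
         body_silhouette = isTRUE(body_silhouette),
         funnel_release = isTRUE(funnel_release),
         subject_id = subject_id, task_id = task_id,
         seed = as.integer(seed)),
    class = "plume_scenario"
  )
  validate_scenario(sc)
  sc
}

#' @export
print.plume_scenario <- function(x, ...) {
  cat(sprintf(
    "<plume_scenario> %g s task + %g s, %g fps, %d x %d px at %g m/px, noise sd %g, seed %d\n",
    x$task_duration_s, x$post_task_s, x$fps, x$frame_size_px[1],
    x$frame_size_px[2], x$metres_per_pixel, x$noise_sd, x$seed))
  invisible(x)
}

scenario_times <- function(sc) {
  nf <- round((sc$task_duration_s + sc$post_task_s) * sc$fps) + 1L
  (seq_len(nf) - 1L) / sc$fps - sc$task_duration_s
}

truth_curve <- function(p, t, task_duration_s) {
  d0 <- p$A * (1 - exp(-task_duration_s / p$tau))
  d <- ifelse(t <= 0,
              p$A * (1 - exp(-(t + task_duration_s) / p$tau)),
              d0 + p$drift * t)
  pmax(d, 0)
}

#' Ground-truth extent curves of a scenario
#'
#' @param scenario A [plume_scenario()].
#' @return A `ground_truth` data frame: `time_s` (t = 0 at task end, start
#'   of task negative) and metric extents `x_front`, `y_diameter`, `z_up`,
#'   `z_down`.
#' @export
plume_truth <- function(scenario) {
  t <- scenario_times(scenario)
  out <- data.frame(time_s = t)
  for (dir in c("x_front", "y_diameter", "z_up", "z_down")) {
    out[[dir]] <- truth_curve(scenario$expansion_params[[dir]], t,
                              scenario$task_duration_s)
  }
  class(out) <- c("ground_truth", "data.frame")
  out
}

# Fixed artifact geometry (0-based pixel rectangles), chosen to be disjoint
# from any admissible plume bounding box (validated below).
artifact_rects <- function(sc) {
  nr <- sc$frame_size_px[1]
  nc <- sc$frame_size_px[2]
  oc <- sc$origin_px[2]
  or_ <- sc$origin_px[1]
  list(
    body = c(x0 = 2, x1 = max(3, oc - 10), y0 = max(0, or_ - 40), y1 = nr - 5),
    reflection = c(x0 = nc - 25, x1 = nc - 5, y0 = nr - 17, y1 = nr - 5),
    funnel_release = c(x0 = nc - 49, x1 = nc - 9, y0 = 4, y1 = 24)
  )
}

rect_polygon <- function(r) {
  cbind(x = c(r["x0"], r["x1"], r["x1"], r["x0"]),
        y = c(r["y0"], r["y0"], r["y1"], r["y1"]))
}

rects_overlap <- function(a, b) {
  a["x0"] <= b["x1"] && b["x0"] <= a["x1"] &&
    a["y0"] <= b["y1"] && b["y0"] <= a["y1"]
}

# Per-frame pixel half-extents of the plume in each direction.
truth_px <- function(sc) {
  truth <- plume_truth(sc)
  eps <- 1e-9
  m <- sc$metres_per_pixel
  list(
    x = floor(truth$x_front / m + eps),
    yh = floor(truth$y_diameter / 2 / m + eps),
    zu = floor(truth$z_up / m + eps),
    zd = floor(truth$z_down / m + eps),
    time_s = truth$time_s
  )
}

validate_scenario <- function(sc) {
  for (dir in c("x_front", "y_diameter", "z_up", "z_down")) {
    p <- sc$expansion_params[[dir]]
    if (is.null(p$A) || is.null(p$tau) || is.null(p$drift))
      stop("expansion_params$", dir, " must have A, tau and drift")
    if (p$A < 0) stop("expansion_params$", dir, ": A must be >= 0")
    if (p$tau <= 0) stop("expansion_params$", dir, ": tau must be > 0")
  }
  if (sc$fps <= 0) stop("fps must be > 0")
  if (sc$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(sc$frame_size_px < 16L))
    stop("frame_size_px must be at least 16 x 16")
  nr <- sc$frame_size_px[1]
  nc <- sc$frame_size_px[2]
  or_ <- sc$origin_px[1]
  oc <- sc$origin_px[2]
  if (or_ < 0 || or_ > nr - 1 || oc < 0 || oc > nc - 1)
    stop("origin_px must lie inside the frame")
  px <- truth_px(sc)
  checks <- list(
    x_front = oc + px$x > nc - 1,
    y_diameter = (or_ - px$yh < 0) | (or_ + px$yh > nr - 1),
    z_up = or_ - px$zu < 0,
    z_down = or_ + px$zd > nr - 1
  )
  for (dir in names(checks)) {
    bad <- which(checks[[dir]])
    if (length(bad) > 0L)
      stop(sprintf(
        "scenario invalid: %s extent leaves the frame at frame %d (t = %.2f s)",
        dir, bad[1] - 1L, px$time_s[bad[1]]))
  }
  # plume bounding box over all frames, for artifact placement
  bbox <- c(x0 = oc, x1 = oc + max(px$x),
            y0 = or_ - max(px$zu, px$yh), y1 = or_ + max(px$zd, px$yh))
  rects <- artifact_rects(sc)
  pad <- function(r) r + c(-2, 2, -2, 2)
  if (sc$reflection_artifacts && rects_overlap(pad(rects$reflection), bbox))
    stop("scenario invalid: reflection artifact region would touch the plume; ",
         "shrink the expansion or enlarge the frame")
  if (sc$funnel_release && rects_overlap(pad(rects$funnel_release), bbox))
    stop("scenario invalid: funnel release region would touch the plume; ",
         "shrink the expansion or enlarge the frame")
  if (sc$body_silhouette && oc < 14)
    stop("scenario invalid: body silhouette needs the mouth at column >= 14")
  invisible(sc)
}

scenario_masks <- function(sc) {
  rects <- artifact_rects(sc)
  masks <- list()
  if (sc$body_silhouette) {
    for (v in c("C1_side", "C3_top"))
      masks[[length(masks) + 1L]] <-
        exclusion_mask(v, list(rect_polygon(rects$body)), "body")
  }
  if (sc$reflection_artifacts) {
    masks[[length(masks) + 1L]] <-
      exclusion_mask("C1_side", list(rect_polygon(rects$reflection)),
                     "reflection")
  }
  if (sc$funnel_release) {
    for (v in c("C1_side", "C3_top"))
      masks[[length(masks) + 1L]] <-
        exclusion_mask(v, list(rect_polygon(rects$funnel_release)),
                       "funnel_release")
  }
  masks
}

scenario_scale_bars <- function(sc) {
  nr <- sc$frame_size_px[1]
  nc <- sc$frame_size_px[2]
  m <- sc$metres_per_pixel
  hlen <- min(100, nc - 16)
  vlen <- min(100, nr - 16)
  bars <- list(
    list(p1 = c(8, nr - 6), p2 = c(8 + hlen, nr - 6), length_m = hlen * m),
    list(p1 = c(6, 8), p2 = c(6, 8 + vlen), length_m = vlen * m)
  )
  list(C1_side = bars, C3_top = bars)
}

render_view <- function(sc, view, px) {
  nr <- sc$frame_size_px[1]
  nc <- sc$frame_size_px[2]
  or_ <- sc$origin_px[1]
  oc <- sc$origin_px[2]
  nf <- length(px$x)
  bg <- sc$background_intensity
  rects <- artifact_rects(sc)
  art_idx <- integer(0)
  art_val <- integer(0)
  add_art <- function(rect, intensity) {
    rr <- rasterize_masks(
      exclusion_mask(view, list(rect_polygon(rect)), "body"),
      c(nr, nc))
    idx <- which(rr)
    art_idx <<- c(art_idx, idx)
    art_val <<- c(art_val, rep(as.integer(intensity), length(idx)))
  }
  if (sc$body_silhouette) add_art(rects$body, 235L)
  if (sc$reflection_artifacts && view == "C1_side")
    add_art(rects$reflection, 200L)
  if (sc$funnel_release) add_art(rects$funnel_release, 220L)

  base <- matrix(as.integer(bg), nr, nc)
  base[art_idx] <- art_val
  frames <- array(0L, dim = c(nr, nc, nf))
  for (f in seq_len(nf)) {
    fr <- base
    xe <- px$x[f]
    re_lo <- if (view == "C1_side") px$zu[f] else px$yh[f]
    re_hi <- if (view == "C1_side") px$zd[f] else px$yh[f]
    if (xe > 0L || re_lo > 0L || re_hi > 0L) {
      cols <- (oc:(oc + xe)) + 1L                       # 1-based
      rows <- ((or_ - re_lo):(or_ + re_hi)) + 1L
      dx <- (cols - 1L) - oc
      dr <- (rows - 1L) - or_                           # positive = down
      tx <- ifelse(dx == 0, 0, (dx / xe)^2)
      se <- ifelse(dr < 0, re_lo, re_hi)
      tr <- ifelse(dr == 0, 0, (dr / se)^2)
      inside <- outer(tr, tx, "+") <= 1 + 1e-12
      sub <- fr[rows, cols, drop = FALSE]
      sub[inside] <- sc$plume_intensity
      fr[rows, cols] <- sub
    }
    # plumes below one pixel in every direction are not rendered
    if (sc$noise_sd > 0) {
      fr <- fr + as.integer(round(rnorm(nr * nc, 0, sc$noise_sd)))
      fr[fr < 0L] <- 0L
      fr[fr > 255L] <- 255L
    }
    frames[, , f] <- fr
  }
  frames
}

#' Generate a synthetic two-view plume recording with ground truth
#'
#' Renders the scenario as a side view (columns = frontal x, rows =
#' vertical z, up = decreasing row) and a top view (columns = frontal x,
#' rows = lateral y, symmetric about the origin row).  The plume is a
#' filled half-ellipse anchored at the mouth whose directional pixel maxima
#' track the ground-truth curves to within one pixel at every frame.
#' Optional bright artifacts (body silhouette, floor reflection, detached
#' funnel-release cloud) are rendered strictly inside the returned
#' exclusion polygons, so masking restores the clean scenario exactly.
#' All randomness derives from `scenario$seed`; the output is bit-identical
#' across runs with the same seed.
#'
#' @param scenario A [plume_scenario()].
#' @return A `plume_scene` list:
#'   \describe{
#'     \item{side_view, top_view}{[frame_sequence()] objects (C1/C3).}
#'     \item{truth}{[plume_truth()] data frame.}
#'     \item{masks}{List of [exclusion_mask()] covering the artifacts.}
#'     \item{calibration}{List `side`/`top` of [view_calibration()].}
#'     \item{scale_bars}{Per-view scale-bar metadata for
#'       [calibrate_view()] round trips.}
#'     \item{scenario}{The input scenario.}
#'   }
#' @export
generate_plume_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "plume_scenario"))
  validate_scenario(scenario)
  px <- truth_px(scenario)
  task_end <- round(scenario$task_duration_s * scenario$fps)
  frames <- withr::with_seed(scenario$seed, {
    list(side = render_view(scenario, "C1_side", px),
         top = render_view(scenario, "C3_top", px))
  })
  mk_seq <- function(arr, view) {
    frame_sequence(arr, fps = scenario$fps, view_id = view,
                   subject_id = scenario$subject_id,
                   task_id = scenario$task_id,
                   task_end_frame = task_end)
  }
  m <- scenario$metres_per_pixel
  cal <- function(view) {
    view_calibration(view, m, m, scenario$origin_px)
  }
  structure(
    list(side_view = mk_seq(frames$side, "C1_side"),
         top_view = mk_seq(frames$top, "C3_top"),
         truth = plume_truth(scenario),
         masks = scenario_masks(scenario),
         calibration = list(side = cal("C1_side"), top = cal("C3_top")),
         scale_bars = scenario_scale_bars(scenario),
         scenario = scenario),
    class = "plume_scene"
  )
}

#' Synthetic harmonic tone audio
#'
#' Sum of sinusoids at integer multiples of `f0` with the given amplitudes,
#' plus optional white Gaussian noise — a fixture for LTAS analysis.  The
#' result is scaled down if needed so the peak amplitude never exceeds 1.
#'
#' @param f0 Fundamental frequency, Hz (must be below `fs / 2`).
#' @param harmonic_amplitudes Numeric vector; element k is the amplitude of
#'   the harmonic at `k * f0`.  All harmonics must lie below `fs / 2`.
#' @param duration_s Duration in seconds (>= 1).
#' @param fs Sampling rate, Hz.
#' @param noise_sd White-noise amplitude SD (before peak normalization).
#' @param seed Optional seed for the noise.
#' @return A `wav` object (see [read_wav()]).
#' @export
generate_tone_audio <- function(f0, harmonic_amplitudes, duration_s,
                                fs = 44100, noise_sd = 0, seed = NULL) {
  if (f0 <= 0 || f0 >= fs / 2)
    stop("f0 must lie in (0, fs/2)")
  if (duration_s < 1) stop("duration_s must be at least 1 second")
  k_active <- which(harmonic_amplitudes != 0)
  if (any(k_active * f0 >= fs / 2))
    stop(sprintf("harmonic %d at %g Hz would alias (fs/2 = %g Hz)",
                 max(k_active), max(k_active) * f0, fs / 2))
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  x <- numeric(n)
  for (k in k_active)
    x <- x + harmonic_amplitudes[k] * sin(2 * pi * k * f0 * t)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(n, 0, noise_sd)
             else withr::with_seed(seed, rnorm(n, 0, noise_sd))
    x <- x + noise
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  structure(list(samples = x, fs = fs), class = "wav")
}
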