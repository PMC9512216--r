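mask_from_pixels <- function(nr, nc, rows0, cols0, meta = list()) {
  m <- matrix(FALSE, nr, nc)
  m[cbind(rows0 + 1L, cols0 + 1L)] <- TRUE
  structure(
    list(masks = array(m, dim = c(nr, nc, 1L)), threshold_used = 128,
         area_px = sum(m), min_component_area_px = 0L, polarity = "bright",
         fps = meta$fps %||% 25, view_id = meta$view_id %||% "C1_side",
         subject_id = "S1", task_id = "T1", task_end_frame = 0L),
    class = "cloud_mask")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scale-bar calibration computes and averages metre-per-pixel ratios", {
  cal <- calibrate_view(
    list(list(p1 = c(10, 50), p2 = c(110, 50), length_m = 1.0),
         list(p1 = c(5, 10), p2 = c(5, 90), length_m = 0.8)),
    view_id = "C1_side", origin_px = c(30, 20))
  expect_equal(cal$metres_per_pixel_h, 0.01)
  expect_equal(cal$metres_per_pixel_v, 0.01)

  cal2 <- calibrate_view(
    list(list(p1 = c(0, 0), p2 = c(100, 0), length_m = 1.0),
         list(p1 = c(0, 10), p2 = c(100, 10), length_m = 1.2),
         list(p1 = c(0, 0), p2 = c(0, 50), length_m = 0.5)),
    view_id = "C1_side", origin_px = c(10, 10))
  expect_equal(cal2$metres_per_pixel_h, 0.011)

  expect_error(
    calibrate_view(list(list(p1 = c(0, 0), p2 = c(100, 0), length_m = 1.0)),
                   view_id = "C1_side", origin_px = c(0, 0)),
    "vertical")
  expect_error(
    calibrate_view(list(list(p1 = c(5, 5), p2 = c(5, 5), length_m = 1.0)),
                   view_id = "C1_side", origin_px = c(0, 0)),
    "zero pixel length")
})

test_that("generator round trip recovers the declared calibration exactly", {
  scene <- generate_plume_scenario(small_scenario())
  for (view in c("C1_side", "C3_top")) {
    bars <- scene$scale_bars[[view]]
    cal <- calibrate_view(bars, view, scene$scenario$origin_px)
    expect_equal(cal$metres_per_pixel_h, scene$scenario$metres_per_pixel)
    expect_equal(cal$metres_per_pixel_v, scene$scenario$metres_per_pixel)
  }
})

test_that("extent extraction follows the arithmetic on constructed masks", {
  cal <- view_calibration("C1_side", 0.01, 0.01, origin_px = c(60, 40))
  # blob spanning cols origin+10 .. origin+110 at the origin row
  cm <- mask_from_pixels(120, 160, rep(60L, 101L), 50:150)
  es <- extract_extents(cm, cal)
  expect_equal(es$x_front[1], 1.10)
  expect_equal(es$z_up[1], 0)
  expect_equal(es$z_down[1], 0)

  # top view: blob spanning rows 40..139 -> diameter (139 - 40 + 1) px
  cal_top <- view_calibration("C3_top", 0.01, 0.01, origin_px = c(90, 40))
  cm_top <- mask_from_pixels(180, 160, 40:139, rep(60L, 100L),
                             meta = list(view_id = "C3_top"))
  et <- extract_extents(cm_top, cal_top)
  expect_equal(et$y_diameter[1], 1.00)
  expect_true(is.na(et$x_front[1]))  # top view does not own x

  # empty mask -> all-zero extents
  e0 <- extract_extents(mask_from_pixels(120, 160, integer(0), integer(0)), cal)
  expect_equal(e0$x_front[1], 0)
  expect_equal(e0$z_up[1], 0)

  # pixels strictly behind the mouth clamp to zero
  eb <- extract_extents(mask_from_pixels(120, 160, 60L, 10L), cal)
  expect_equal(eb$x_front[1], 0)

  expect_error(extract_extents(cm_top, cal), "view_id")
})

test_that("extents scale with calibration and shift with the origin", {
  cm <- mask_from_pixels(120, 160, c(50L, 70L), c(90L, 100L))
  cal1 <- view_calibration("C1_side", 0.01, 0.01, c(60, 40))
  cal2 <- view_calibration("C1_side", 0.02, 0.02, c(60, 40))
  e1 <- extract_extents(cm, cal1)
  e2 <- extract_extents(cm, cal2)
  for (col in c("x_front", "z_up", "z_down"))
    expect_equal(e2[[col]], 2 * e1[[col]])
  # moving the origin forward by k columns removes k * m/px of x_front
  cal3 <- view_calibration("C1_side", 0.01, 0.01, c(60, 45))
  e3 <- extract_extents(cm, cal3)
  expect_equal(e3$x_front, e1$x_front - 5 * 0.01)
})

test_that("task-end alignment sets the paper time convention and is idempotent", {
  sc <- small_scenario()
  scene <- generate_plume_scenario(sc)
  cm <- segment_cloud(scene$side_view, 128, 0)
  es <- extract_extents(cm, scene$calibration$side)
  aligned <- align_to_task_end(es)
  expect_equal(aligned$time_s[1], -sc$task_duration_s)
  expect_equal(aligned$time_s[scene$side_view$task_end_frame + 1L], 0)
  expect_equal(max(aligned$time_s), sc$post_task_s)
  expect_identical(align_to_task_end(aligned), aligned)

  zero <- align_to_task_end(es, task_end_frame = 0)
  expect_true(all(zero$time_s >= 0))
  expect_error(align_to_task_end(es, task_end_frame = nrow(es)), "task_end_frame")
})

test_that("merge_views combines directions, trims time, and checks fps", {
  scene <- generate_plume_scenario(small_scenario())
  side <- align_to_task_end(
    extract_extents(segment_cloud(scene$side_view, 128, 0),
                    scene$calibration$side))
  top <- align_to_task_end(
    extract_extents(segment_cloud(scene$top_view, 128, 0),
                    scene$calibration$top))
  merged <- merge_views(side, top)
  expect_equal(nrow(merged), nrow(side))
  expect_setequal(attr(merged, "directions"),
                  c("x_front", "y_diameter", "z_up", "z_down"))

  short <- top[1:(nrow(top) - 5L), , drop = FALSE]
  attributes(short) <- c(attributes(short),
                         attributes(top)[c("fps", "subject_id", "task_id",
                                           "task_end_frame", "directions",
                                           "aligned")])
  class(short) <- class(top)
  merged2 <- merge_views(side, short)
  expect_equal(nrow(merged2), nrow(side) - 5L)

  bad <- top
  attr(bad, "fps") <- 30
  expect_error(merge_views(side, bad), "fps mismatch")

  # a missing view is tolerated: remaining directions only
  only_side <- merge_views(side = side, top = NULL)
  expect_setequal(attr(only_side, "directions"), c("x_front", "z_up", "z_down"))
  expect_error(merge_views(NULL, NULL), "at least one view")
})

test_that("noise-free end-to-end extents match truth within one pixel", {
  scene <- generate_plume_scenario(small_scenario())
  res <- track_dispersion(scene$side_view, scene$top_view,
                          scene$calibration$side, scene$calibration$top,
                          min_component_area_px = 0, smooth = FALSE)
  m <- scene$scenario$metres_per_pixel
  expect_equal(res$time_s, scene$truth$time_s)
  expect_series_close(res, scene$truth,
                      c("x_front", "y_diameter", "z_up", "z_down"), m + 1e-9)
})
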