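test_that("zero-emission scenario renders uniform background and zero truth", {
  sc <- small_scenario()
  sc$expansion_params <- lapply(sc$expansion_params, function(p) {
    p$A <- 0; p$drift <- 0; p
  })
  scene <- generate_plume_scenario(sc)
  expect_true(all(scene$side_view$frames == 20L))
  expect_true(all(scene$top_view$frames == 20L))
  expect_true(all(scene$truth$x_front == 0))
  expect_true(all(scene$truth$y_diameter == 0))
})

test_that("ground-truth curve matches its closed form and invariants", {
  sc <- plume_scenario(
    task_duration_s = 8, post_task_s = 2, fps = 25,
    expansion_params = list(
      x_front    = list(A = 1.0, tau = 2, drift = 0),
      y_diameter = list(A = 0.5, tau = 2, drift = 0),
      z_up       = list(A = 0.4, tau = 2, drift = 0),
      z_down     = list(A = 0.3, tau = 2, drift = 0)
    ),
    noise_sd = 0
  )
  truth <- plume_truth(sc)
  i0 <- which(truth$time_s == 0)
  expect_length(i0, 1L)                       # t = 0 present
  expect_equal(truth$x_front[i0], 1.0 * (1 - exp(-4)), tolerance = 1e-12)
  expect_equal(truth$x_front[1], 0)           # task start
  expect_true(all(diff(truth$time_s) > 0))
  expect_true(all(as.matrix(truth[-1]) >= 0))
  # drift continues linearly after task end
  sc$expansion_params$x_front$drift <- 0.05
  truth2 <- plume_truth(sc)
  expect_equal(truth2$x_front[nrow(truth2)],
               1.0 * (1 - exp(-4)) + 0.05 * 2, tolerance = 1e-12)
})

test_that("rendered extents track ground truth within one pixel per frame", {
  scene <- generate_plume_scenario(small_scenario())
  m <- scene$scenario$metres_per_pixel
  org <- scene$scenario$origin_px
  for (f in seq_len(n_frames(scene$side_view))) {
    side <- scene$side_view$frames[, , f] >= 128L
    top <- scene$top_view$frames[, , f] >= 128L
    es <- oracle_frame_extents(side, org)
    et <- oracle_frame_extents(top, org)
    expect_lte(abs(es["x"] * m - scene$truth$x_front[f]), m)
    expect_lte(abs(es["zu"] * m - scene$truth$z_up[f]), m)
    expect_lte(abs(es["zd"] * m - scene$truth$z_down[f]), m)
    expect_lte(abs(et["yspan"] * m - scene$truth$y_diameter[f]), m)
    # both views agree on the frontal extent
    expect_equal(unname(es["x"]), unname(et["x"]))
  }
})

test_that("generation is bit-identical for a fixed seed", {
  sc <- small_scenario()
  sc$noise_sd <- 8
  a <- generate_plume_scenario(sc)
  b <- generate_plume_scenario(sc)
  expect_identical(a$side_view$frames, b$side_view$frames)
  expect_identical(a$top_view$frames, b$top_view$frames)
  sc$seed <- 99L
  c_ <- generate_plume_scenario(sc)
  expect_false(identical(a$side_view$frames, c_$side_view$frames))
})

test_that("scenarios whose extents leave the frame are rejected by direction", {
  sc <- small_scenario()
  sc$expansion_params$x_front$A <- 5
  expect_error(generate_plume_scenario(sc), "x_front")
  sc <- small_scenario()
  sc$expansion_params$z_up$A <- 2
  expect_error(generate_plume_scenario(sc), "z_up")
  expect_error(plume_scenario(fps = -1), "fps")
  expect_error(plume_scenario(expansion_params = list(
    x_front = list(A = -1, tau = 1, drift = 0),
    y_diameter = list(A = 0, tau = 1, drift = 0),
    z_up = list(A = 0, tau = 1, drift = 0),
    z_down = list(A = 0, tau = 1, drift = 0))), "A must be")
})

test_that("artifacts lie inside their declared exclusion polygons", {
  sc <- small_scenario(body_silhouette = TRUE, reflection_artifacts = TRUE,
                       funnel_release = TRUE)
  scene <- generate_plume_scenario(sc)
  clean <- generate_plume_scenario(small_scenario())
  d <- dim(scene$side_view$frames)
  for (view in c("side_view", "top_view")) {
    vid <- scene[[view]]$view_id
    vmasks <- Filter(function(m) m$view_id == vid, scene$masks)
    excl <- rasterize_masks(vmasks, d[1:2])
    # every pixel differing from the clean render lies inside a polygon
    diff_px <- which(apply(scene[[view]]$frames != clean[[view]]$frames,
                           c(1, 2), any))
    expect_true(all(diff_px %in% which(excl)))
  }
})

test_that("tone generator produces the requested harmonics", {
  wav <- generate_tone_audio(1475, c(1), duration_s = 1, fs = 44100)
  t <- (0:(44099)) / 44100
  expect_equal(wav$samples, sin(2 * pi * 1475 * t), tolerance = 1e-12)
  expect_lte(max(abs(wav$samples)), 1)

  silence <- generate_tone_audio(1000, c(0, 0), duration_s = 1)
  expect_true(all(silence$samples == 0))

  # two equal harmonics scaled to unit peak keep equal relative amplitude
  two <- generate_tone_audio(2000, c(1, 1), duration_s = 1)
  expect_lte(max(abs(two$samples)), 1)

  expect_error(generate_tone_audio(30000, c(1), 1), "f0")
  expect_error(generate_tone_audio(12000, c(1, 1), 1), "alias")
  expect_error(generate_tone_audio(1000, c(1), 0.5), "duration")
})
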