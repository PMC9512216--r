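constant_series <- function(values, task = "T1", fps = 25,
                            subjects = paste0("S", seq_along(values)),
                            t = seq(-2, 10, by = 1 / fps)) {
  lapply(seq_along(values), function(i) {
    df <- data.frame(time_s = t, x_front = values[i],
                     y_diameter = values[i] / 2,
                     z_up = NA_real_, z_down = NA_real_)
    structure(df, class = c("extent_series", "data.frame"), fps = fps,
              subject_id = subjects[i], task_id = task,
              task_end_frame = sum(t < 0), aligned = TRUE,
              directions = c("x_front", "y_diameter"))
  })
}

test_that("summary table computes cross-subject medians and maxima", {
  one <- summarize_dispersion(constant_series(0.7), timepoints_s = c(0, 3))
  expect_equal(unique(one$value_m), 0.7 * c(1, 0.5))
  expect_equal(one$n_subjects, rep(1L, nrow(one)))

  five <- summarize_dispersion(constant_series(c(0.8, 1.0, 1.2, 1.3, 1.4)))
  x0 <- five[five$dimension == "x_front" & five$timepoint_s == 0, ]
  expect_equal(x0$value_m[x0$statistic == "median"], 1.2)
  expect_equal(x0$value_m[x0$statistic == "maximum"], 1.4)
  # even subject count: mean of the central pair
  four <- summarize_dispersion(constant_series(c(1, 2, 4, 8)))
  expect_equal(four$value_m[four$dimension == "x_front" &
                            four$statistic == "median"][1], 3)
  # maximum >= median everywhere
  expect_true(all(
    five$value_m[five$statistic == "maximum"] >=
      five$value_m[five$statistic == "median"]))
})

test_that("summary is subject-permutation invariant and max never decreases", {
  series <- constant_series(c(0.5, 0.9, 1.1))
  a <- summarize_dispersion(series)
  b <- summarize_dispersion(rev(series))
  expect_equal(a, b)
  more <- summarize_dispersion(c(series, constant_series(2.0,
                                                         subjects = "S9")))
  expect_true(all(
    more$value_m[more$statistic == "maximum"] >=
      a$value_m[a$statistic == "maximum"]))
})

test_that("timepoints outside a series are reported with the subject", {
  short <- constant_series(1, t = seq(-2, 5, by = 0.04))
  expect_error(summarize_dispersion(short, timepoints_s = c(0, 10)),
               "subject S1")
})

test_that("median curve equals the per-timepoint brute-force median", {
  same <- constant_series(c(0.4, 0.4, 0.4))
  mc <- median_curve(same)
  expect_equal(mc$x_front, same[[1]]$x_front)

  three <- constant_series(c(0.2, 0.4, 0.9))
  expect_true(all(median_curve(three)$x_front == 0.4))

  withr::with_seed(41, {
    t <- seq(-1, 2, by = 0.04)
    rand <- lapply(1:5, function(i) {
      df <- data.frame(time_s = t, x_front = runif(length(t)),
                       y_diameter = runif(length(t)),
                       z_up = NA_real_, z_down = NA_real_)
      structure(df, class = c("extent_series", "data.frame"), fps = 25,
                subject_id = paste0("S", i), task_id = "T1",
                task_end_frame = 25L, aligned = TRUE,
                directions = c("x_front", "y_diameter"))
    })
  })
  mc <- median_curve(rand)
  for (k in seq_along(t)) {
    expect_equal(mc$x_front[k],
                 median(vapply(rand, function(s) s$x_front[k], numeric(1))))
  }
  bad <- rand[[1]]
  attr(bad, "fps") <- 30
  expect_error(median_curve(list(rand[[2]], bad)), "fps")
})

test_that("comparison markup matches printed examples and the inclusive rule", {
  expect_equal(classify_vs_reference(0.97, 0.83)$mark, "higher")
  expect_equal(classify_vs_reference(0.90, 1.12)$mark, "lower")
  expect_equal(classify_vs_reference(1.31, 1.35)$mark, "comparable")
  # inclusive at exactly 0.1 m (the printed 0.62 vs 0.72 cell is bold)
  expect_equal(classify_vs_reference(0.62, 0.72)$mark, "lower")
  expect_equal(classify_vs_reference(0.72, 0.62)$mark, "higher")
  expect_equal(classify_vs_reference(0.71, 0.62)$mark, "comparable")
  expect_equal(classify_vs_reference(0.62, 0.72)$difference_m, -0.10)
  expect_error(classify_vs_reference(0.5, 0.5, tolerance_m = -1), "tolerance")
  expect_error(classify_vs_reference(-0.5, 0.5), "non-negative")
})

test_that("difference reporting reads table cells exactly", {
  tbl <- recorder_dispersion_table()
  cell <- function(task, dim, stat, tp)
    list(task = task, dimension = dim, statistic = stat, timepoint_s = tp)
  d <- report_differences(tbl, list(
    list(a = cell("T1", "x_front", "maximum", 10),
         b = cell("T3", "x_front", "maximum", 10)),
    list(a = cell("T1", "y_diameter", "maximum", 10),
         b = cell("T2", "y_diameter", "maximum", 10)),
    list(a = cell("T1", "x_front", "median", 0),
         b = cell("T1", "x_front", "median", 0))
  ))
  expect_equal(d$difference_m, c(0.41, 0.48, 0))
  expect_error(
    report_differences(tbl, list(list(a = cell("T9", "x_front", "median", 0),
                                      b = cell("T1", "x_front", "median", 0)))),
    "not found")
})

test_that("the bundled reference table is internally consistent", {
  tbl <- recorder_dispersion_table()
  expect_equal(nrow(tbl), 72L)
  agg <- tapply(tbl$value_m, list(tbl$task, tbl$dimension, tbl$timepoint_s,
                                  tbl$statistic), identity)
  for (task in unique(tbl$task)) for (dim in unique(tbl$dimension))
    for (tp in unique(tbl$timepoint_s)) {
      expect_gte(agg[task, dim, as.character(tp), "maximum"],
                 agg[task, dim, as.character(tp), "median"])
    }
})
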