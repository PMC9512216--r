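# Independent brute-force oracles and small fixtures shared by the tests.
# Oracles deliberately re-derive results from first principles (sorting,
# double loops, per-pixel arithmetic) and never call the package code paths
# they are used to check.

# Sliding median: symmetric shrink at boundaries, interior even windows
# span offsets -(w/2-1)..w/2, even-count medians = mean of central pair.
oracle_moving_median <- function(x, window) {
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i - 1L < half_lo || n - i < half_hi) {
      r <- min(i - 1L, n - i)
      w <- x[(i - r):(i + r)]
    } else {
      w <- x[(i - half_lo):(i + half_hi)]
    }
    s <- sort(w)
    m <- length(s)
    out[i] <- if (m %% 2L == 1L) s[(m + 1L) %/% 2L]
              else (s[m %/% 2L] + s[m %/% 2L + 1L]) / 2
  }
  out
}

oracle_mse <- function(a, b) {
  stopifnot(length(a) == length(b))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  acc / length(a)
}

# Connected components by repeated flood fill over an explicit visit queue.
oracle_component_areas <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  areas <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || seen[r, c]) next
    area <- 0L
    queue <- list(c(r, c))
    seen[r, c] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      area <- area + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- p[1] + dr
        c2 <- p[2] + dc
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
    areas <- c(areas, area)
  }
  areas
}

# Small, fast scenario used throughout the unit tests: 2 s task observed
# for 2 s more on a 120 x 160 grid (well inside the frame bounds).
small_scenario <- function(...) {
  plume_scenario(
    task_duration_s = 2, post_task_s = 2, fps = 25,
    frame_size_px = c(120L, 160L), origin_px = c(60, 40),
    metres_per_pixel = 0.01,
    expansion_params = list(
      x_front    = list(A = 0.60, tau = 1,   drift = 0.01),
      y_diameter = list(A = 0.40, tau = 1.2, drift = 0),
      z_up       = list(A = 0.30, tau = 1.5, drift = 0),
      z_down     = list(A = 0.20, tau = 1.5, drift = 0)
    ),
    noise_sd = 0, seed = 7L, ...
  )
}

# Measured pixel extents of one binary frame, computed per pixel.
oracle_frame_extents <- function(mask, origin_rc0) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(c(x = 0, zu = 0, zd = 0, yspan = 0))
  r0 <- idx[, 1] - 1
  c0 <- idx[, 2] - 1
  c(x = max(0, max(c0 - origin_rc0[2])),
    zu = max(0, max(origin_rc0[1] - r0)),
    zd = max(0, max(r0 - origin_rc0[1])),
    yspan = max(r0) - min(r0) + 1)
}

expect_series_close <- function(measured, truth, cols, tol) {
  for (col in cols) {
    expect_lt(max(abs(measured[[col]] - truth[[col]])), tol,
              label = sprintf("max |measured - truth| for %s", col))
  }
}
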