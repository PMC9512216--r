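#' Construct an exclusion mask
#'
#' Exclusion masks remove regions that must never be segmented as cloud:
#' uncovered body parts (hands, faces), specular reflections, and — for the
#' suction-funnel task — the vapor cloud re-released at the funnel outlet,
#' which does not originate from the player.
#'
#' Polygon vertices use 0-based image coordinates: `x` = column, `y` = row,
#' row 0 at the top.  A pixel whose centre lies inside a polygon (even-odd
#' rule; boundary counts as inside) is excluded.
#'
#' @param view_id View the mask applies to (`"C1_side"` or `"C3_top"`).
#' @param polygons List of `n x 2` matrices (columns `x`, `y`), each with at
#'   least 3 vertices.
#' @param role One of `"body"`, `"funnel_release"`, `"reflection"`.
#' @return An `exclusion_mask` object.
#' @export
exclusion_mask <- function(view_id = c("C1_side", "C3_top"), polygons,
                           role = c("body", "funnel_release", "reflection")) {
  view_id <- match.arg(view_id)
  role <- match.arg(role)
  if (!is.list(polygons)) polygons <- list(polygons)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each polygon must be an n x 2 matrix with >= 3 vertices")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  structure(list(view_id = view_id, polygons = polygons, role = role),
            class = "exclusion_mask")
}

#' @export
print.exclusion_mask <- function(x, ...) {
  cat(sprintf("<exclusion_mask> %s / %s: %d polygon(s)\n",
              x$view_id, x$role, length(x$polygons)))
  invisible(x)
}

#' Rasterize exclusion masks onto a pixel grid
#'
#' @param masks A single `exclusion_mask` or a list of them.
#' @param dim Frame dimensions `c(rows, cols)`.
#' @return Logical matrix, `TRUE` where pixels are excluded.
#' @export
rasterize_masks <- function(masks, dim) {
  if (inherits(masks, "exclusion_mask")) masks <- list(masks)
  polys <- list()
  for (m in masks) {
    for (p in m$polygons) {
      if (any(p[, "x"] < 0 | p[, "x"] > dim[2] - 1 |
              p[, "y"] < 0 | p[, "y"] > dim[1] - 1))
        stop(sprintf("polygon (role %s) extends outside the %d x %d frame",
                     m$role, dim[1], dim[2]))
      polys[[length(polys) + 1L]] <- p
    }
  }
  if (length(polys) == 0L)
    return(matrix(FALSE, dim[1], dim[2]))
  polygon_raster(dim[1], dim[2], polys)
}

# Modal intensity of the four 10x10 (or smaller) frame corners: a robust
# estimate of the background level, used as the default fill so masked
# regions can never segment as cloud.
estimate_background <- function(frame) {
  nr <- nrow(frame)
  nc <- ncol(frame)
  k <- min(10L, nr, nc)
  corners <- c(frame[1:k, 1:k], frame[1:k, (nc - k + 1L):nc],
               frame[(nr - k + 1L):nr, 1:k],
               frame[(nr - k + 1L):nr, (nc - k + 1L):nc])
  tab <- tabulate(corners + 1L, nbins = 256L)
  which.max(tab) - 1L
}

#' Apply exclusion masks to frames
#'
#' Sets every pixel inside any matching polygon to `fill`; all other pixels
#' are unchanged.  Masking is idempotent.
#'
#' @param x A `frame_sequence` or a single integer frame matrix.
#' @param masks List of [exclusion_mask()] objects (masks whose `view_id`
#'   differs from the sequence's are rejected).
#' @param fill Intensity for excluded pixels.  Default `NULL` estimates the
#'   modal background level from the corners of the first frame.
#' @return Object of the same type with excluded pixels filled.
#' @export
apply_exclusion_masks <- function(x, masks, fill = NULL) {
  if (inherits(masks, "exclusion_mask")) masks <- list(masks)
  if (inherits(x, "frame_sequence")) {
    masks <- Filter(function(m) {
      if (!inherits(m, "exclusion_mask")) stop("masks must be exclusion_mask objects")
      if (m$view_id != x$view_id)
        stop(sprintf("mask view_id %s does not match sequence view_id %s",
                     m$view_id, x$view_id))
      TRUE
    }, masks)
    if (length(masks) == 0L) return(x)
    d <- dim(x$frames)
    excl <- rasterize_masks(masks, d[1:2])
    if (!any(excl)) return(x)
    if (is.null(fill)) fill <- estimate_background(x$frames[, , 1])
    idx <- which(excl)
    npix <- d[1] * d[2]
    full <- rep(idx, d[3]) + rep((seq_len(d[3]) - 1L) * npix, each = length(idx))
    x$frames[full] <- as.integer(fill)
    x
  } else if (is.matrix(x)) {
    if (length(masks) == 0L) return(x)
    excl <- rasterize_masks(masks, dim(x))
    if (is.null(fill)) fill <- estimate_background(x)
    x[excl] <- as.integer(fill)
    x
  } else {
    stop("x must be a frame_sequence or an integer matrix")
  }
}

#' Write exclusion masks to JSON
#'
#' The format is one JSON array of objects
#' `{"view": "C1_side", "role": "body", "polygons": [[[x, y], ...], ...]}`
#' with 0-based pixel coordinates.
#'
#' @param masks List of [exclusion_mask()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_masks <- function(masks, path) {
  if (inherits(masks, "exclusion_mask")) masks <- list(masks)
  payload <- lapply(masks, function(m) {
    list(view = m$view_id, role = m$role,
         polygons = lapply(m$polygons, function(p) unname(p)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read exclusion masks from JSON
#'
#' @param path JSON path in the format written by [write_exclusion_masks()].
#' @return List of [exclusion_mask()] objects.
#' @export
read_exclusion_masks <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(m) {
    polys <- lapply(m$polygons, function(p) {
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    })
    exclusion_mask(view_id = m$view, polygons = polys, role = m$role)
  })
}
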