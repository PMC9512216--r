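## Minimal 8-bit PNG / PGM codecs.
##
## No image-IO package is available at run time, and the formats needed here
## are narrow: 8-bit grayscale (and, for input only, 8-bit RGB) PNG without
## interlacing, plus NetPBM graymaps.  PNG's IDAT payload is a zlib stream,
## which base R's memCompress()/memDecompress() produce and consume
## directly; chunk CRCs come from the compiled crc32_raw().

PNG_SIGNATURE <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

int_to_raw_be <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

raw_to_int_be <- function(r) {
  sum(as.integer(r) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_raw_be(length(data)), body, crc32_raw(body))
}

#' Write an 8-bit PNG image
#'
#' Writes a grayscale matrix (or an `rows x cols x 3` RGB array) of
#' intensities in `[0, 255]` as a non-interlaced 8-bit PNG.
#'
#' @param img Integer matrix (grayscale) or 3-d array with third dimension 3
#'   (RGB); values in `[0, 255]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_png()], [write_frames()]
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) {
    colortype <- 0L
    nr <- nrow(img)
    nc <- ncol(img)
    scan <- rbind(0L, t(img))       # prepend filter byte 0 to each scanline
  } else if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) {
    colortype <- 2L
    nr <- dim(img)[1]
    nc <- dim(img)[2]
    x <- aperm(img, c(3L, 2L, 1L))  # channel fastest, then column, then row
    dim(x) <- c(3L * nc, nr)
    scan <- rbind(0L, x)
  } else {
    stop("img must be a matrix or a rows x cols x 3 array")
  }
  v <- as.integer(scan)
  if (anyNA(v) || any(v < 0L | v > 255L))
    stop("image intensities must be integers in [0, 255]")
  ihdr <- c(
    int_to_raw_be(nc), int_to_raw_be(nr),
    as.raw(c(8L, colortype, 0L, 0L, 0L))
  )
  idat <- memCompress(as.raw(v), type = "gzip")
  out <- c(
    PNG_SIGNATURE,
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}

png_paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a)
  pb <- abs(p - b)
  pc <- abs(p - c)
  if (pa <= pb && pa <= pc) a else if (pb <= pc) b else c
}

#' Read an 8-bit PNG image
#'
#' Supports non-interlaced 8-bit grayscale and RGB images (the subset
#' written by [write_png()] plus standard scanline filters).
#'
#' @param path PNG file path.
#' @return Integer matrix (grayscale) or `rows x cols x 3` integer array
#'   (RGB), values in `[0, 255]`.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 8L || !identical(bytes[1:8], PNG_SIGNATURE))
    stop("not a PNG file: ", path)
  pos <- 9L
  idat <- list()
  width <- height <- bitdepth <- colortype <- NULL
  while (pos + 7L <= length(bytes)) {
    len <- raw_to_int_be(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data_start <- pos + 8L
    data <- if (len > 0L) bytes[data_start:(data_start + len - 1L)] else raw(0)
    if (type == "IHDR") {
      width <- raw_to_int_be(data[1:4])
      height <- raw_to_int_be(data[5:8])
      bitdepth <- as.integer(data[9])
      colortype <- as.integer(data[10])
      if (bitdepth != 8L || !(colortype %in% c(0L, 2L)))
        stop("unsupported PNG (need 8-bit grayscale or RGB): ", path)
      if (as.integer(data[13]) != 0L)
        stop("interlaced PNG not supported: ", path)
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") {
      break
    }
    pos <- data_start + len + 4L
  }
  if (is.null(width)) stop("PNG missing IHDR: ", path)
  raw_scan <- memDecompress(do.call(c, idat), type = "gzip")
  bpp <- if (colortype == 0L) 1L else 3L
  stride <- width * bpp + 1L
  scan <- matrix(as.integer(raw_scan), nrow = stride, ncol = height)
  filters <- scan[1L, ]
  rows <- scan[-1L, , drop = FALSE]
  if (any(filters != 0L)) {
    prev <- integer(width * bpp)
    for (r in seq_len(height)) {
      cur <- rows[, r]
      f <- filters[r]
      if (f == 1L) {
        for (i in seq_len(width * bpp)) {
          left <- if (i > bpp) cur[i - bpp] else 0L
          cur[i] <- (cur[i] + left) %% 256L
        }
      } else if (f == 2L) {
        cur <- (cur + prev) %% 256L
      } else if (f == 3L) {
        for (i in seq_len(width * bpp)) {
          left <- if (i > bpp) cur[i - bpp] else 0L
          cur[i] <- (cur[i] + (left + prev[i]) %/% 2L) %% 256L
        }
      } else if (f == 4L) {
        for (i in seq_len(width * bpp)) {
          left <- if (i > bpp) cur[i - bpp] else 0L
          ul <- if (i > bpp) prev[i - bpp] else 0L
          cur[i] <- (cur[i] + png_paeth(left, prev[i], ul)) %% 256L
        }
      } else if (f != 0L) {
        stop("unsupported PNG filter type ", f)
      }
      rows[, r] <- cur
      prev <- cur
    }
  }
  if (colortype == 0L) {
    t(rows)  # rows are scanlines
  } else {
    aperm(array(rows, dim = c(3L, width, height)), c(3L, 2L, 1L))
  }
}

#' Write a binary PGM (P5) graymap
#'
#' @param img Integer matrix with values in `[0, 255]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  v <- as.integer(t(img))
  if (anyNA(v) || any(v < 0L | v > 255L))
    stop("image intensities must be integers in [0, 255]")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img))), con)
  writeBin(as.raw(v), con)
  invisible(path)
}

#' Read a PGM (P2 or P5) graymap
#'
#' @param path PGM file path.
#' @return Integer matrix with values in `[0, 255]`.
#' @export
read_pgm <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  txt_head <- rawToChar(bytes[seq_len(min(length(bytes), 128L))])
  magic <- substr(txt_head, 1L, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header = magic, width, height, maxval as whitespace-separated tokens,
  # then a single whitespace byte before the raster (P5)
  is_space <- as.integer(bytes) %in% c(9L, 10L, 13L, 32L)
  tokens <- character(0)
  i <- 3L
  while (length(tokens) < 3L && i <= length(bytes)) {
    while (i <= length(bytes) && is_space[i]) i <- i + 1L
    if (i <= length(bytes) && bytes[i] == charToRaw("#")) {
      while (i <= length(bytes) && bytes[i] != as.raw(10L)) i <- i + 1L
      next
    }
    j <- i
    while (j <= length(bytes) && !is_space[j]) j <- j + 1L
    tokens <- c(tokens, rawToChar(bytes[i:(j - 1L)]))
    i <- j
  }
  dims <- as.integer(tokens)
  if (length(dims) != 3L || anyNA(dims)) stop("malformed PGM header: ", path)
  width <- dims[1]
  height <- dims[2]
  if (magic == "P5") {
    i <- i + 1L  # single whitespace after maxval
    v <- as.integer(bytes[i:(i + width * height - 1L)])
  } else {
    v <- as.integer(scan(text = rawToChar(bytes[i:length(bytes)]),
                         quiet = TRUE))
    v <- v[seq_len(width * height)]
  }
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}
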