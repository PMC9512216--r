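## Minimal RIFF/WAVE PCM codec (mono or multichannel, 16/24-bit).
## Samples are exchanged as doubles in [-1, 1].

#' Write a PCM WAV file
#'
#' @param samples Numeric vector of samples in `[-1, 1]` (values outside are
#'   clipped), or a `wav` object from [read_wav()].
#' @param path Output file path.
#' @param fs Sampling rate in Hz.
#' @param bits Bits per sample, 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, fs = 44100, bits = 16L) {
  if (inherits(samples, "wav")) {
    fs <- samples$fs
    samples <- samples$samples
  }
  if (!bits %in% c(16L, 24L)) stop("bits must be 16 or 24")
  x <- pmax(-1, pmin(1, as.numeric(samples)))
  full <- 2^(bits - 1) - 1
  q <- as.integer(round(x * full))
  bytes_per <- bits %/% 8L
  n <- length(q)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- n * bytes_per
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeBin(charToRaw("data"), con)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 16L) {
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    b <- rbind(q %% 256L, (q %/% 256L) %% 256L, (q %/% 65536L) %% 256L)
    b[3L, q < 0L] <- (q[q < 0L] %/% 65536L) %% 256L  # two's complement kept by %%
    writeBin(as.raw(as.vector(b %% 256L)), con)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Supports uncompressed PCM, 16 or 24 bits per sample.  Multichannel input
#' is averaged down to mono.
#'
#' @param path WAV file path.
#' @return A `wav` object: list with `samples` (numeric in `[-1, 1]`) and
#'   `fs` (Hz).
#' @export
read_wav <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (rawToChar(bytes[1:4]) != "RIFF" || rawToChar(bytes[9:12]) != "WAVE")
    stop("not a RIFF/WAVE file: ", path)
  u16 <- function(i) sum(as.integer(bytes[i:(i + 1L)]) * c(1, 256))
  u32 <- function(i) sum(as.integer(bytes[i:(i + 3L)]) * c(1, 256, 65536, 16777216))
  pos <- 13L
  fs <- NULL; bits <- NULL; nchan <- NULL; data <- NULL
  while (pos + 7L <= length(bytes)) {
    cid <- rawToChar(bytes[pos:(pos + 3L)])
    csize <- u32(pos + 4L)
    body <- pos + 8L
    if (cid == "fmt ") {
      fmt <- u16(body)
      if (fmt != 1L) stop("only uncompressed PCM WAV is supported")
      nchan <- u16(body + 2L)
      fs <- u32(body + 4L)
      bits <- u16(body + 14L)
    } else if (cid == "data") {
      data <- bytes[body:(body + csize - 1L)]
    }
    pos <- body + csize + (csize %% 2L)  # chunks are word-aligned
  }
  if (is.null(fs) || is.null(data)) stop("WAV missing fmt or data chunk")
  if (!bits %in% c(16L, 24L)) stop("only 16- or 24-bit PCM is supported")
  if (bits == 16L) {
    v <- readBin(data, integer(), n = length(data) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
    x <- v / 32767
  } else {
    m <- matrix(as.integer(data[seq_len((length(data) %/% 3L) * 3L)]),
                nrow = 3L)
    v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388607
  }
  if (nchan > 1L) {
    nfrm <- length(x) %/% nchan
    x <- colMeans(matrix(x[seq_len(nfrm * nchan)], nrow = nchan))
  }
  structure(list(samples = x, fs = fs), class = "wav")
}

#' @export
print.wav <- function(x, ...) {
  cat(sprintf("<wav> %d samples, %.3f s at %d Hz\n",
              length(x$samples), length(x$samples) / x$fs, x$fs))
  invisible(x)
}
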