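hann_window <- function(n) {
  # periodic Hann window, the standard choice for Welch-style averaging
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

#' Long-term average spectrum (LTAS)
#'
#' Welch-style averaged spectrum: the signal is cut into Hanning-windowed
#' frames of `nfft` samples advanced by `hop`, the per-frame power spectra
#' are averaged, and the mean power is converted to dB relative to the
#' spectrum's own maximum (peak-normalized, so only spectral shape is
#' compared), clipped below at `floor_db`.  Defaults follow the common
#' speech-analysis convention: 512-point Hanning FFT and a -110 dB display
#' floor at 44.1 kHz.
#'
#' @param audio Numeric sample vector in `[-1, 1]`, or a `wav` object from
#'   [read_wav()].
#' @param fs Sampling rate in Hz; required for a bare numeric vector.  If
#'   `audio` is a `wav` object and `fs` is also given, the two must agree.
#' @param nfft FFT length (default 512).
#' @param hop Frame advance in samples (default `nfft / 2`).
#' @param floor_db Lower clip level in dB (default -110).
#' @return An `ltas_spectrum` object: data frame with `freq_hz` (the
#'   `nfft/2 + 1` non-negative FFT bin frequencies) and `level_db`, plus
#'   attributes `fs`, `nfft`, `floor_db`.
#' @export
compute_ltas <- function(audio, fs = NULL, nfft = 512L, hop = nfft %/% 2L,
                         floor_db = -110) {
  if (inherits(audio, "wav")) {
    if (!is.null(fs) && !isTRUE(all.equal(fs, audio$fs)))
      stop(sprintf("declared fs (%g Hz) does not match the recording (%g Hz)",
                   fs, audio$fs))
    fs <- audio$fs
    audio <- audio$samples
  }
  if (is.null(fs)) fs <- 44100
  n <- length(audio)
  if (n < nfft)
    stop(sprintf("audio too short: %d samples, need at least nfft = %d",
                 n, nfft))
  starts <- seq(1L, n - nfft + 1L, by = hop)
  w <- hann_window(nfft)
  frames <- matrix(audio[outer(0:(nfft - 1L), starts, "+")], nrow = nfft)
  spec <- stats::mvfft(frames * w)
  pow <- rowMeans(Mod(spec)^2)[1:(nfft %/% 2L + 1L)]
  pmax_ <- max(pow)
  level <- if (pmax_ <= 0) {
    rep(floor_db, length(pow))
  } else {
    pmax(10 * log10(pow / pmax_), floor_db)
  }
  structure(
    data.frame(freq_hz = (0:(nfft %/% 2L)) * fs / nfft, level_db = level),
    class = c("ltas_spectrum", "data.frame"),
    fs = fs, nfft = nfft, floor_db = floor_db
  )
}

#' @export
print.ltas_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ltas_spectrum> %d bins, 0-%.0f Hz (fs %.0f Hz, nfft %d), floor %g dB\n",
    nrow(x), max(x$freq_hz), attr(x, "fs"), attr(x, "nfft"),
    attr(x, "floor_db")))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(attr(a, "fs"), attr(b, "fs"))) ||
      !identical(attr(a, "nfft"), attr(b, "nfft")) ||
      nrow(a) != nrow(b))
    stop("spectra are on different frequency grids (fs/nfft mismatch)")
}

#' Average LTAS spectra across players
#'
#' Per-bin arithmetic mean of the dB levels — the across-player curve shown
#' when comparing the same task with and without safety devices.
#'
#' @param spectra List of `ltas_spectrum` objects on identical grids.
#' @return An `ltas_spectrum` with the averaged levels.
#' @export
average_spectra <- function(spectra) {
  if (inherits(spectra, "ltas_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0L) stop("at least one spectrum is required")
  ref <- spectra[[1]]
  for (s in spectra[-1]) check_same_grid(ref, s)
  levels <- rowMeans(vapply(spectra, function(s) s$level_db,
                            numeric(nrow(ref))))
  ref$level_db <- levels
  ref
}

#' Mean squared error between two LTAS curves
#'
#' Mean over frequency bins of the squared dB difference; the scalar used
#' to quantify how much a safety device changes the instrument's spectrum.
#' Symmetric, non-negative, zero iff the curves are identical.
#'
#' @param a,b `ltas_spectrum` objects on the same grid.
#' @return Mean squared error in dB^2.
#' @export
ltas_mse <- function(a, b) {
  check_same_grid(a, b)
  mean((a$level_db - b$level_db)^2)
}

#' Write an LTAS spectrum to CSV
#' @param spectrum An `ltas_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ltas <- function(spectrum, path) {
  df <- as.data.frame(spectrum)
  df$fs <- attr(spectrum, "fs")
  df$nfft <- attr(spectrum, "nfft")
  df$floor_db <- attr(spectrum, "floor_db")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an LTAS spectrum from CSV written by [write_ltas()]
#' @param path CSV path.
#' @return An `ltas_spectrum`.
#' @export
read_ltas <- function(path) {
  df <- read.csv(path)
  structure(
    data.frame(freq_hz = df$freq_hz, level_db = df$level_db),
    class = c("ltas_spectrum", "data.frame"),
    fs = df$fs[1], nfft = as.integer(df$nfft[1]), floor_db = df$floor_db[1]
  )
}
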