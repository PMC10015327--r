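#' Waveform container and PCM WAV I/O
#'
#' Audio is carried as a \code{"waveform"}: a numeric sample vector in
#' [-1, 1] plus a sample rate. Files are 16-bit PCM mono WAV, written and
#' parsed directly (RIFF chunking) so the pipeline has no external audio
#' dependency.
#'
#' @name waveform
NULL

#' Construct a waveform
#'
#' @param samples numeric vector, finite, |sample| <= 1.
#' @param rate sample rate in Hz, positive.
#' @return object of class \code{"waveform"}.
#' @export
waveform <- function(samples, rate) {
  if (rate <= 0) stop("rate must be positive")
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (length(samples) > 0 && max(abs(samples)) > 1 + 1e-9)
    stop("clipping: |sample| > 1")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a \code{"waveform"}.
#' @export
wav_duration <- function(w) length(w$samples) / w$rate

#' Root-mean-square amplitude
#' @param x a \code{"waveform"} or numeric vector.
#' @export
rms <- function(x) {
  s <- if (inherits(x, "waveform")) x$samples else x
  sqrt(mean(s^2))
}

#' Band-limited RMS via the discrete Fourier transform
#'
#' Parseval-consistent RMS of the signal content between two frequencies;
#' used to mix and to verify call-to-background SNR.
#'
#' @param x waveform or numeric vector.
#' @param rate sample rate (taken from the waveform if given).
#' @param f_lo,f_hi band edges in Hz.
#' @export
band_rms <- function(x, f_lo, f_hi, rate = NULL) {
  if (inherits(x, "waveform")) { rate <- x$rate; x <- x$samples }
  n <- length(x)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * rate / n
  freqs[freqs > rate / 2] <- rate - freqs[freqs > rate / 2]  # mirror half
  keep <- freqs >= f_lo & freqs <= f_hi
  sqrt(sum(Mod(sp[keep])^2) / n^2)
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' @param w a \code{"waveform"}.
#' @param path output file.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  s <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(round(s * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return a \code{"waveform"}.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such audio file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  rate <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM supported")
      if (fmt[2] != 1) stop("only mono supported")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", n = sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      samples <- pcm / 32767
    } else {
      readBin(con, "raw", n = sz)
    }
    if (!is.null(rate) && !is.null(samples)) break
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV: ", path)
  waveform(samples, rate)
}
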