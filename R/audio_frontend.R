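#' Spectro-temporal frontend
#'
#' Log-Mel spectrograms (the detector input) and segmentation of long
#' recordings into fixed-length analysis windows.
#'
#' @name audio_frontend
NULL

#' Log-Mel configuration
#'
#' Defaults: 25 ms STFT frames with 10 ms hop, 64 Mel bands between 100 Hz
#' and 12 kHz (capped at Nyquist).
#'
#' @param window_s,hop_s STFT frame length and hop in seconds.
#' @param n_mels number of Mel bands (>= 8).
#' @param fmin,fmax band-edge frequencies in Hz.
#' @param floor_eps additive floor before the log.
#' @export
logmel_config <- function(window_s = 0.025, hop_s = 0.010, n_mels = 64,
                          fmin = 100, fmax = 12000, floor_eps = 1e-10) {
  if (n_mels < 8) stop("n_mels must be >= 8")
  if (hop_s <= 0 || window_s < hop_s) stop("need window_s >= hop_s > 0")
  list(window_s = window_s, hop_s = hop_s, n_mels = n_mels,
       fmin = fmin, fmax = fmax, floor_eps = floor_eps)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular Mel filterbank over the one-sided FFT bins
mel_filterbank <- function(n_mels, nfft, rate, fmin, fmax) {
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  fpts <- mel_to_hz(mpts)
  bins <- (0:(nfft / 2)) * rate / nfft
  fb <- matrix(0, n_mels, nfft / 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- fpts[m]; cc <- fpts[m + 1]; hi <- fpts[m + 2]
    up <- (bins - lo) / (cc - lo)
    dn <- (hi - bins) / (hi - cc)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "centres") <- fpts[2:(n_mels + 1)]
  fb
}

#' Log-Mel spectrogram
#'
#' Hann-windowed STFT power mapped through a triangular Mel filterbank, with
#' \code{log(power + floor_eps)} so digital silence maps to
#' \code{log(floor_eps)} rather than -Inf. The frame count is
#' \code{ceiling(n_samples / hop_samples)} (the tail is zero-padded).
#'
#' @param w a \code{"waveform"}.
#' @param config a \code{\link{logmel_config}}; \code{fmax} is validated
#'   against Nyquist.
#' @return list of class \code{"spectrogram"}: \code{values} (frames x Mel
#'   bands), \code{frame_times} (s, frame centres), \code{config},
#'   \code{rate}, and the filterbank centre frequencies as attribute
#'   \code{"mel_centres"}.
#' @export
logmel <- function(w, config = logmel_config()) {
  rate <- w$rate
  if (config$fmax > rate / 2) stop("fmax exceeds Nyquist")
  win <- max(2, round(config$window_s * rate))
  hop <- max(1, round(config$hop_s * rate))
  x <- w$samples
  if (length(x) < win) stop("waveform shorter than one STFT window")
  n_frames <- ceiling(length(x) / hop)
  xp <- c(x, numeric(max(0, (n_frames - 1) * hop + win - length(x))))
  nfft <- 2^ceiling(log2(win))
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  starts <- (seq_len(n_frames) - 1) * hop
  frames <- matrix(0, nfft, n_frames)
  for (f in seq_len(n_frames))
    frames[seq_len(win), f] <- xp[starts[f] + seq_len(win)] * hann
  sp <- stats::mvfft(frames)
  power <- Mod(sp[seq_len(nfft / 2 + 1), , drop = FALSE])^2
  fb <- mel_filterbank(config$n_mels, nfft, rate, config$fmin,
                       min(config$fmax, rate / 2))
  melpow <- t(fb %*% power)                    # frames x mels
  vals <- log(melpow + config$floor_eps)
  structure(list(values = vals,
                 frame_times = (starts + win / 2) / rate,
                 config = config, rate = rate),
            mel_centres = attr(fb, "centres"),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("log-Mel spectrogram: %d frames x %d bands (%.2f s)\n",
              nrow(x$values), ncol(x$values), max(x$frame_times)))
  invisible(x)
}

#' Segment a recording into overlapping analysis windows
#'
#' Every sample belongs to at least one window; for a recording of duration
#' at least one window the count is
#' \code{ceiling((duration - window) / hop) + 1}. A recording shorter than
#' one window yields a single zero-padded window, flagged.
#'
#' @param w a \code{"waveform"} (or a WAV path, read on the fly).
#' @param window,hop window length and hop in seconds; need
#'   \code{window >= hop > 0}.
#' @param file source identifier carried on each window.
#' @return list of analysis windows: \code{file}, \code{start}, \code{end}
#'   (s), \code{samples}, \code{padded} flag.
#' @export
window_stream <- function(w, window = 3, hop = 1.5, file = "recording") {
  if (is.character(w)) { file <- basename(w); w <- read_wav(w) }
  if (hop <= 0 || hop > window) stop("need window >= hop > 0")
  n_win <- round(window * w$rate)
  n_hop <- round(hop * w$rate)
  n <- length(w$samples)
  if (n < n_win) {
    return(list(list(file = file, start = 0, end = window,
                     samples = c(w$samples, numeric(n_win - n)),
                     rate = w$rate, padded = TRUE)))
  }
  n_windows <- ceiling((n - n_win) / n_hop) + 1
  lapply(seq_len(n_windows), function(i) {
    i0 <- (i - 1) * n_hop + 1
    i1 <- i0 + n_win - 1
    padded <- i1 > n
    seg <- if (padded) c(w$samples[i0:n], numeric(i1 - n)) else w$samples[i0:i1]
    list(file = file, start = (i0 - 1) / w$rate, end = (i0 - 1) / w$rate + window,
         samples = seg, rate = w$rate, padded = padded)
  })
}
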