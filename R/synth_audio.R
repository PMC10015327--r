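#' Synthetic soundscapes with whinny-like calls
#'
#' Generators for labelled synthetic audio emulating rainforest PAM
#' recordings: a frequency-modulated harmonic "whinny" (0.5-1 s arc,
#' fundamental sweeping roughly 700 to 3500 Hz, 2-4 harmonics, 8-12 Hz
#' amplitude tremolo), acoustically adjacent confounders (reversed or
#' band-shifted sweeps), a pink-noise + insect + transient background bed,
#' full scheduled recordings with events mixed at a requested SNR, and
#' labelled clip sets for detector training.
#'
#' @name synth_audio
NULL

#' The field recording schedule
#'
#' Three daily windows, 05.00-09.30, 14.00-18.30 and 21.00-03.00 (the night
#' window crosses midnight and is written as 21-27 h), totalling 15 h/day.
#'
#' @return list of \code{c(start_h, end_h)} windows.
#' @export
paper_schedule <- function() list(c(5, 9.5), c(14, 18.5), c(21, 27))

#' Total scheduled hours per day
#' @param schedule list of \code{c(start_h, end_h)} windows.
#' @export
schedule_hours <- function(schedule) sum(vapply(schedule, diff, numeric(1)))

#' Synthesize a whinny-like frequency-modulated call
#'
#' A linear FM sweep of the fundamental with \code{n_harmonics} harmonics at
#' 1/k amplitude (harmonics above Nyquist are dropped), sinusoidal amplitude
#' tremolo, and a raised-cosine onset/offset envelope. Peak-normalized to
#' -3 dBFS headroom. Deterministic for a fixed seed (the seed drives only
#' the harmonic starting phases).
#'
#' @param f0_start,f0_end fundamental start and end frequency (Hz), each in
#'   [200, 8000].
#' @param duration call length in seconds, in [0.3, 2.0].
#' @param n_harmonics number of harmonics (>= 1).
#' @param tremolo_rate amplitude-modulation rate in Hz (0 disables).
#' @param rate sample rate (Hz), default 48000.
#' @param seed RNG seed.
#' @return a \code{"waveform"}; the fundamental's spectral peak lies between
#'   \code{min(f0_start, f0_end)} and \code{max(f0_start, f0_end)}.
#' @export
synth_whinny <- function(f0_start = 700, f0_end = 3500, duration = 0.8,
                         n_harmonics = 3, tremolo_rate = 10, rate = 48000,
                         seed = 1) {
  if (f0_start < 200 || f0_start > 8000 || f0_end < 200 || f0_end > 8000)
    stop("fundamental must lie in [200, 8000] Hz")
  if (duration < 0.3 || duration > 2.0)
    stop("duration must lie in [0.3, 2.0] s")
  if (n_harmonics < 1) stop("need at least one harmonic")
  set.seed(seed)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  # linear chirp phase: f(t) = f0 + (f1 - f0) t / d
  sweep_phase <- 2 * pi * (f0_start * t + (f0_end - f0_start) * t^2 / (2 * duration))
  s <- numeric(n)
  for (k in seq_len(n_harmonics)) {
    if (k * max(f0_start, f0_end) >= rate / 2) next  # keep under Nyquist
    phi <- stats::runif(1, 0, 2 * pi)
    s <- s + sin(k * sweep_phase + phi) / k
  }
  if (all(s == 0)) stop("all harmonics above Nyquist; raise the sample rate")
  if (tremolo_rate > 0)
    s <- s * (0.7 + 0.3 * sin(2 * pi * tremolo_rate * t))
  edge <- max(2, round(0.05 * n))
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
  env[seq_len(edge)] <- ramp
  env[n - edge + seq_len(edge)] <- rev(ramp)
  s <- s * env
  s <- s / max(abs(s)) * 10^(-3 / 20)   # -3 dBFS headroom
  waveform(s, rate)
}

#' Synthesize a bird-like confounder sweep
#'
#' Acoustically adjacent hard negative: the same FM-arc machinery as the
#' whinny but with the sweep direction reversed (or band-shifted), so that
#' negatives are not separable by trivial cues.
#'
#' @inheritParams synth_whinny
#' @param band_shift multiplicative shift applied to both band edges.
#' @export
synth_confounder <- function(f0_start = 3500, f0_end = 700, duration = 0.6,
                             n_harmonics = 2, tremolo_rate = 0,
                             band_shift = 1, rate = 48000, seed = 1) {
  synth_whinny(f0_start * band_shift, f0_end * band_shift, duration,
               n_harmonics, tremolo_rate, rate, seed)
}

default_background <- function() {
  list(pink = list(rms = 0.05),
       insects = list(freqs = c(3000), rms = 0.02),
       transients = list(rate_per_s = 0.05, rms = 0.04))
}

#' Synthesize a rainforest-like background bed
#'
#' Pink-noise bed plus narrowband insect tones with slow amplitude drift and
#' sparse broadband transients. The overall RMS is normalized to the
#' root-sum-square of the enabled component levels. All components disabled
#' gives digital silence.
#'
#' @param duration seconds, positive.
#' @param rate sample rate (Hz).
#' @param components list with optional blocks \code{pink} (rms),
#'   \code{insects} (freqs, rms) and \code{transients} (rate_per_s, rms);
#'   see \code{default_background()}.
#' @param seed RNG seed.
#' @return a \code{"waveform"}.
#' @export
synth_background <- function(duration, rate = 48000,
                             components = default_background(), seed = 1) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  n <- round(duration * rate)
  s <- numeric(n)
  target <- 0
  if (!is.null(components$pink) && components$pink$rms > 0) {
    # 1/f spectral shaping of white noise
    white <- stats::rnorm(n)
    sp <- stats::fft(white)
    f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))
    shape <- 1 / sqrt(pmax(f, 1))
    pink <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
    pink <- pink / rms(pink) * components$pink$rms
    s <- s + pink
    target <- target + components$pink$rms^2
  }
  if (!is.null(components$insects) && components$insects$rms > 0) {
    t <- (seq_len(n) - 1) / rate
    tone <- numeric(n)
    for (f0 in components$insects$freqs) {
      if (f0 >= rate / 2) stop("insect tone at/above Nyquist")
      am <- 1 + 0.3 * sin(2 * pi * stats::runif(1, 0.1, 0.5) * t +
                            stats::runif(1, 0, 2 * pi))
      tone <- tone + am * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
    }
    tone <- tone / rms(tone) * components$insects$rms
    s <- s + tone
    target <- target + components$insects$rms^2
  }
  if (!is.null(components$transients) && components$transients$rms > 0) {
    k <- stats::rpois(1, components$transients$rate_per_s * duration)
    tr <- numeric(n)
    if (k > 0) {
      for (i in seq_len(k)) {
        len <- round(stats::runif(1, 0.01, 0.05) * rate)
        at <- sample(max(1, n - len), 1)
        burst <- stats::rnorm(len) * exp(-seq_len(len) / (0.3 * len))
        tr[at:(at + len - 1)] <- tr[at:(at + len - 1)] + burst
      }
      tr <- tr / rms(tr) * components$transients$rms
      s <- s + tr
      target <- target + components$transients$rms^2
    }
  }
  if (target > 0) s <- s / rms(s) * sqrt(target)
  if (max(abs(s)) > 1) s <- s / max(abs(s)) * 0.999
  waveform(s, rate)
}

#' Mix a call into a background segment at a requested SNR
#'
#' The call is scaled so that its band-limited RMS (call band) is
#' \code{snr_db} decibels above the band-limited RMS of the local
#' background. Mixing that would clip (>0 dBFS) raises an error rather than
#' saturating.
#'
#' @param bg background \code{"waveform"} (modified in place and returned).
#' @param call call \code{"waveform"} (same rate).
#' @param at_s call onset within the background, seconds.
#' @param snr_db requested SNR in dB.
#' @param band call band \code{c(f_lo, f_hi)} used for the RMS measurement;
#'   clipped to Nyquist.
#' @return the mixed \code{"waveform"}.
#' @export
mix_at_snr <- function(bg, call, at_s, snr_db, band = c(500, 4000)) {
  stopifnot(bg$rate == call$rate)
  band[2] <- min(band[2], bg$rate / 2 * 0.999)
  i0 <- round(at_s * bg$rate) + 1
  i1 <- i0 + length(call$samples) - 1
  if (i0 < 1 || i1 > length(bg$samples)) stop("call placed outside background")
  seg <- bg$samples[i0:i1]
  bg_level <- band_rms(seg, band[1], band[2], rate = bg$rate)
  if (bg_level == 0) bg_level <- 1e-6   # silent bed: mix against a tiny floor
  call_level <- band_rms(call$samples, band[1], band[2], rate = call$rate)
  gain <- bg_level * 10^(snr_db / 20) / call_level
  out <- bg$samples
  out[i0:i1] <- out[i0:i1] + call$samples * gain
  if (max(abs(out)) > 1)
    stop("clipping: mixed signal exceeds 0 dBFS (snr too high for headroom)")
  waveform(out, bg$rate)
}

#' Render scheduled recordings with placed call events
#'
#' One WAV file per scheduled window per day; events are synthesized and
#' mixed at their requested SNR relative to the local background, and an
#' event manifest (file, onset_s, duration_s, kind, snr_db, site_id) is
#' written alongside.
#'
#' @param schedule list of \code{c(start_h, end_h)} daily windows (end may
#'   exceed 24 for windows crossing midnight); default
#'   \code{\link{paper_schedule}}.
#' @param events data frame with columns day, onset_h (clock hours, on the
#'   same axis as the schedule), duration_s, kind ("whinny"/"confounder"),
#'   snr_db. Zero-row input renders background only.
#' @param rate sample rate (Hz). Desk-scale tests use low rates.
#' @param seed RNG seed.
#' @param dir output directory.
#' @param n_days days to render (default: max event day, else 1).
#' @param site_id recorded in the manifest.
#' @param background components passed to \code{\link{synth_background}}.
#' @return list with \code{files}, \code{manifest} (data frame) and
#'   \code{manifest_path}.
#' @export
render_recording <- function(schedule = paper_schedule(), events = NULL,
                             rate = 48000, seed = 1, dir = tempfile("rec"),
                             n_days = NULL, site_id = "S001",
                             background = default_background()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(events))
    events <- data.frame(day = integer(), onset_h = numeric(),
                         duration_s = numeric(), kind = character(),
                         snr_db = numeric())
  if (is.null(n_days)) n_days <- if (nrow(events) > 0) max(events$day) else 1
  # validate placement before rendering anything
  ev_window <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    hit <- which(vapply(schedule, function(wn)
      events$onset_h[i] >= wn[1] &&
        events$onset_h[i] + events$duration_s[i] / 3600 <= wn[2], logical(1)))
    if (length(hit) == 0)
      stop("placement error: event ", i, " (day ", events$day[i], ", ",
           events$onset_h[i], " h) falls outside every scheduled window")
    ev_window[i] <- hit[1]
  }
  files <- character(0)
  man <- list()
  for (day in seq_len(n_days)) {
    for (wi in seq_along(schedule)) {
      wn <- schedule[[wi]]
      dur_s <- (wn[2] - wn[1]) * 3600
      w <- synth_background(dur_s, rate, background,
                            seed = seed + 1000 * day + wi)
      sel <- which(events$day == day & ev_window == wi)
      fname <- sprintf("%s_day%02d_win%d.wav", site_id, day, wi)
      for (i in sel) {
        ev <- events[i, ]
        call <- if (ev$kind == "whinny") {
          synth_whinny(duration = ev$duration_s, rate = rate,
                       f0_end = min(3500, rate / 2 * 0.9),
                       seed = seed + 7 * i)
        } else {
          synth_confounder(f0_start = min(3500, rate / 2 * 0.9),
                           duration = ev$duration_s, rate = rate,
                           seed = seed + 7 * i)
        }
        onset_s <- (ev$onset_h - wn[1]) * 3600
        w <- mix_at_snr(w, call, onset_s, ev$snr_db)
        man[[length(man) + 1]] <-
          data.frame(file = fname, onset_s = onset_s,
                     duration_s = ev$duration_s, kind = ev$kind,
                     snr_db = ev$snr_db, site_id = site_id, day = day)
      }
      path <- file.path(dir, fname)
      write_wav(w, path)
      files <- c(files, path)
    }
  }
  manifest <- if (length(man) > 0) do.call(rbind, man) else
    data.frame(file = character(), onset_s = numeric(), duration_s = numeric(),
               kind = character(), snr_db = numeric(), site_id = character(),
               day = integer())
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  list(files = files, manifest = manifest, manifest_path = mp)
}

#' Generate a labelled clip set for detector training
#'
#' Positive clips contain exactly one whinny mixed over background at an SNR
#' drawn from \code{snr_range} (spanning faint calls); negatives are
#' background only, except a \code{hard_negative_fraction} that carry a
#' confounder sweep. Site ids are assigned round-robin and each site gets
#' its own insect-band character, so site-independent splits are meaningful.
#' Byte-identical output for a fixed seed.
#'
#' @param n_pos,n_neg positive/negative clip counts (positive).
#' @param hard_negative_fraction fraction of negatives with a confounder.
#' @param n_sites number of sites for round-robin assignment.
#' @param clip_length clip length in seconds; must be at least
#'   \code{max_call_s}.
#' @param rate sample rate (Hz), default 8000 for desk scale.
#' @param snr_range SNR range (dB) for positives.
#' @param max_call_s maximum call duration drawn.
#' @param seed master seed; per-clip seeds are derived from it.
#' @return list of labelled clips, each a list with \code{waveform},
#'   \code{label} ("positive"/"negative"), \code{site_id}, \code{clip_id}
#'   and an \code{events} data frame.
#' @export
make_clipset <- function(n_pos, n_neg, hard_negative_fraction = 0.3,
                         n_sites = 13, clip_length = 1.2, rate = 8000,
                         snr_range = c(5, 30), max_call_s = 1.0, seed = 1) {
  if (n_pos <= 0 || n_neg <= 0) stop("counts must be positive")
  if (hard_negative_fraction < 0 || hard_negative_fraction > 1)
    stop("hard_negative_fraction must be in [0, 1]")
  if (clip_length < max_call_s)
    stop("clip_length shorter than the maximum call duration")
  nyq <- rate / 2
  f_hi <- min(3500, nyq * 0.9)
  total <- n_pos + n_neg
  labels <- c(rep("positive", n_pos), rep("negative", n_neg))
  n_hard <- round(hard_negative_fraction * n_neg)
  hard <- c(rep(FALSE, n_pos), rep(TRUE, n_hard), rep(FALSE, n_neg - n_hard))
  insect_freqs <- 1500 + 150 * (seq_len(n_sites) - 1)
  insect_freqs <- pmin(insect_freqs, nyq * 0.85)
  clips <- vector("list", total)
  for (i in seq_len(total)) {
    site <- ((i - 1) %% n_sites) + 1
    cseed <- seed * 100000 + i
    set.seed(cseed)
    # quiet bed leaves headroom for calls up to ~35 dB SNR without clipping
    bgc <- list(pink = list(rms = 0.01),
                insects = list(freqs = insect_freqs[site], rms = 0.004))
    bg <- synth_background(clip_length, rate, bgc, seed = cseed)
    ev <- data.frame(onset_s = numeric(), duration_s = numeric(),
                     kind = character(), snr_db = numeric())
    w <- bg
    if (labels[i] == "positive") {
      dur <- stats::runif(1, 0.5, max_call_s)
      snr <- stats::runif(1, snr_range[1], snr_range[2])
      onset <- stats::runif(1, 0, clip_length - dur)
      call <- synth_whinny(f0_start = 700, f0_end = f_hi, duration = dur,
                           n_harmonics = sample(2:4, 1),
                           tremolo_rate = stats::runif(1, 8, 12),
                           rate = rate, seed = cseed + 1)
      w <- mix_at_snr(bg, call, onset, snr, band = c(500, f_hi))
      ev <- data.frame(onset_s = onset, duration_s = dur, kind = "whinny",
                       snr_db = snr)
    } else if (hard[i]) {
      dur <- stats::runif(1, 0.4, 0.8)
      snr <- stats::runif(1, snr_range[1], snr_range[2])
      onset <- stats::runif(1, 0, clip_length - dur)
      call <- synth_confounder(f0_start = f_hi, f0_end = 700, duration = dur,
                               rate = rate, seed = cseed + 1)
      w <- mix_at_snr(bg, call, onset, snr, band = c(500, f_hi))
      ev <- data.frame(onset_s = onset, duration_s = dur, kind = "confounder",
                       snr_db = snr)
    }
    clips[[i]] <- list(waveform = w, label = labels[i],
                       site_id = sprintf("S%02d", site),
                       clip_id = sprintf("clip%05d", i), events = ev)
  }
  clips
}

#' Clip-set manifest
#'
#' @param clips output of \code{\link{make_clipset}}.
#' @return data frame (clip_id, site_id, label, onset_s, duration_s, kind,
#'   snr_db), one row per clip (event columns NA for event-free negatives).
#' @export
clipset_manifest <- function(clips) {
  do.call(rbind, lapply(clips, function(cl) {
    if (nrow(cl$events) > 0) {
      cbind(data.frame(clip_id = cl$clip_id, site_id = cl$site_id,
                       label = cl$label), cl$events)
    } else {
      data.frame(clip_id = cl$clip_id, site_id = cl$site_id, label = cl$label,
                 onset_s = NA_real_, duration_s = NA_real_,
                 kind = NA_character_, snr_db = NA_real_)
    }
  }))
}
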