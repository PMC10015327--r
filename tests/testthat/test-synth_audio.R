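test_that("degenerate FM collapses to a pure tone with the right FFT peak", {
  w <- synth_whinny(f0_start = 1000, f0_end = 1000, duration = 0.5,
                    n_harmonics = 1, tremolo_rate = 0, rate = 8000, seed = 1)
  sp <- Mod(stats::fft(w$samples))
  half <- seq_len(length(sp) %/% 2)
  peak_hz <- (which.max(sp[half]) - 1) * w$rate / length(sp)
  expect_lt(abs(peak_hz - 1000), 5)
})

test_that("whinny sweep has a monotonically increasing frequency track", {
  w <- synth_whinny(700, 3500, duration = 0.8, n_harmonics = 3, rate = 8000,
                    seed = 1)
  f <- inst_freq(w)
  # trim envelope edges, smooth with a running median
  core <- f[round(0.1 * length(f)):round(0.9 * length(f))]
  sm <- stats::runmed(core, 201)
  expect_gt(stats::cor(sm, seq_along(sm), method = "spearman"), 0.95)
  expect_gt(sm[length(sm)], sm[1])
})

test_that("whinny parameter validation", {
  expect_error(synth_whinny(duration = 0.1), "duration")
  expect_error(synth_whinny(f0_start = 100), "fundamental")
  expect_error(synth_whinny(f0_end = 9000), "fundamental")
})

test_that("background components behave and determinism holds", {
  z <- synth_background(0.5, rate = 4000,
                        components = list(pink = NULL, insects = NULL,
                                          transients = NULL), seed = 1)
  expect_true(all(z$samples == 0))
  p1 <- synth_background(0.5, 4000, list(pink = list(rms = 0.05)), seed = 3)
  p2 <- synth_background(0.5, 4000, list(pink = list(rms = 0.05)), seed = 3)
  expect_identical(p1$samples, p2$samples)
  expect_lt(abs(rms(p1) - 0.05) / 0.05, 0.05)
  tone <- synth_background(0.5, 16000,
                           list(insects = list(freqs = 6000, rms = 0.05)),
                           seed = 1)
  sp <- Mod(stats::fft(tone$samples))
  half <- seq_len(length(sp) %/% 2)
  peak_hz <- (which.max(sp[half]) - 1) * tone$rate / length(sp)
  expect_lt(abs(peak_hz - 6000), 20)
})

test_that("mixed-call SNR is honoured within 1 dB", {
  rate <- 4000
  bg <- synth_background(2, rate, list(pink = list(rms = 0.01)), seed = 5)
  call <- synth_whinny(700, 1800, 0.6, rate = rate, seed = 2)
  for (snr in c(5, 20)) {
    mixed <- mix_at_snr(bg, call, 0.5, snr, band = c(500, 1800))
    i0 <- round(0.5 * rate) + 1
    i1 <- i0 + length(call$samples) - 1
    got <- 20 * log10(
      band_rms(mixed$samples[i0:i1] - bg$samples[i0:i1], 500, 1800, rate) /
        band_rms(bg$samples[i0:i1], 500, 1800, rate))
    expect_lt(abs(got - snr), 1)
  }
})

test_that("recording schedule renders one file per window and 15 h/day", {
  expect_equal(schedule_hours(paper_schedule()), 15)
  out <- render_recording(rate = 8, seed = 1, n_days = 1,
                          background = list(pink = list(rms = 0.02)))
  expect_length(out$files, 3)
  total_s <- sum(vapply(out$files,
                        function(f) wav_duration(read_wav(f)), numeric(1)))
  expect_equal(total_s, 15 * 3600)
  expect_equal(nrow(out$manifest), 0)
})

test_that("rendered events raise band energy and the manifest round-trips", {
  sched <- list(c(5, 5.05))   # 3-minute window for speed
  ev <- data.frame(day = 1, onset_h = 5 + 10 / 3600, duration_s = 0.8,
                   kind = "whinny", snr_db = 20)
  out <- render_recording(sched, ev, rate = 4000, seed = 2,
                          background = list(pink = list(rms = 0.01)))
  w <- read_wav(out$files[1])
  bg <- render_recording(sched, NULL, rate = 4000, seed = 2,
                         background = list(pink = list(rms = 0.01)))
  wb <- read_wav(bg$files[1])
  seg <- function(x) x$samples[(10 * 4000):(11 * 4000)]
  expect_gt(band_rms(seg(w), 500, 1999, 4000),
            3 * band_rms(seg(wb), 500, 1999, 4000))
  man2 <- utils::read.csv(out$manifest_path)
  expect_equal(man2$onset_s, out$manifest$onset_s)
  expect_equal(man2$kind, out$manifest$kind)
  # placement outside every window errors
  bad <- data.frame(day = 1, onset_h = 12, duration_s = 0.5, kind = "whinny",
                    snr_db = 10)
  expect_error(render_recording(sched, bad, rate = 4000), "placement")
})

test_that("clipset counts, sites, determinism and validation", {
  clips <- make_clipset(24, 24, hard_negative_fraction = 0.5, n_sites = 13,
                        clip_length = 1.2, rate = 2000, seed = 4)
  expect_length(clips, 48)
  expect_equal(sum(vapply(clips, function(cl) cl$label == "positive",
                          logical(1))), 24)
  expect_length(unique(vapply(clips, function(cl) cl$site_id, character(1))),
                13)
  m1 <- clipset_manifest(clips)
  m2 <- clipset_manifest(make_clipset(24, 24, hard_negative_fraction = 0.5,
                                      n_sites = 13, clip_length = 1.2,
                                      rate = 2000, seed = 4))
  expect_identical(m1, m2)
  # hard_negative_fraction = 0 -> no confounder events in negatives
  clips0 <- make_clipset(6, 6, hard_negative_fraction = 0, n_sites = 3,
                         rate = 2000, seed = 5)
  negs <- Filter(function(cl) cl$label == "negative", clips0)
  expect_true(all(vapply(negs, function(cl) nrow(cl$events) == 0, logical(1))))
  expect_error(make_clipset(5, 5, clip_length = 0.5), "clip_length")
  expect_error(make_clipset(0, 5), "counts")
})

test_that("easy clipset is linearly separable by band energy alone", {
  clips <- easy_clipset()
  feat <- vapply(clips, function(cl)
    band_rms(cl$waveform, 600, 1900), numeric(1))
  lab <- vapply(clips, function(cl) cl$label == "positive", logical(1))
  expect_gt(min(feat[lab]), max(feat[!lab]))
})

test_that("WAV round trip preserves samples to 16-bit precision", {
  w <- synth_whinny(700, 1800, 0.5, rate = 4000, seed = 9)
  path <- tempfile(fileext = ".wav")
  write_wav(w, path)
  w2 <- read_wav(path)
  expect_equal(w2$rate, 4000)
  expect_lt(max(abs(w2$samples - w$samples)), 1 / 32767)
  # a re-written decoded file is bit-exact
  path2 <- tempfile(fileext = ".wav")
  write_wav(w2, path2)
  expect_identical(read_wav(path2)$samples, w2$samples)
  expect_error(waveform(c(0, 2), 100), "clipping")
})
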