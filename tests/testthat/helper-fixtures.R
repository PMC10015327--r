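# shared fixtures, built once per test run (everything is generated in code;
# no binary fixtures ship with the package)

.fixtures <- new.env()

# the "easy" clipset: high SNR, no hard negatives -- band energy alone
# separates it, so the detector test surface is solvable by construction
easy_clipset <- function() {
  if (is.null(.fixtures$clips))
    .fixtures$clips <- make_clipset(n_pos = 60, n_neg = 60,
                                    hard_negative_fraction = 0, n_sites = 6,
                                    clip_length = 1.2, rate = 4000,
                                    snr_range = c(20, 30), seed = 11)
  .fixtures$clips
}

desk_ml_config <- function() logmel_config(n_mels = 32, fmax = 1999)

trained_easy_model <- function() {
  if (is.null(.fixtures$model)) {
    sp <- split_site_independent(easy_clipset(), seed = 1)
    cfg <- detector_config(conv_channels = c(8, 16), epochs = 8,
                           batch_size = 16, seed = 2)
    m <- build_model(cfg, n_mels = 32)
    .fixtures$model <- train_detector(m, sp$train, sp$validation,
                                      desk_ml_config())
    .fixtures$split <- sp
  }
  list(model = .fixtures$model, split = .fixtures$split)
}

# independent brute-force Moran's I oracle (explicit double loop)
moran_brute <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w[i, j] * z[i] * z[j]
    s0 <- s0 + w[i, j]
  }
  (n / s0) * num / sum(z^2)
}

# instantaneous frequency by the analytic signal (FFT Hilbert transform)
inst_freq <- function(w) {
  x <- w$samples
  n <- length(x)
  sp <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  z <- stats::fft(sp * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- atan2(sin(dph), cos(dph))     # unwrap
  dph * w$rate / (2 * pi)
}
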