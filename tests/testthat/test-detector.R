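tiny_model <- function(seed = 7) {
  cfg <- detector_config(conv_channels = c(4, 6), se_reduction = 2,
                         attention_heads = 2, dropout = 0, epochs = 1,
                         seed = seed)
  build_model(cfg, n_mels = 8)
}

test_that("analytic gradients match finite differences", {
  set.seed(3)
  m <- tiny_model()
  S <- matrix(stats::rnorm(80), 10, 8)
  y <- 1
  fw <- pamscape:::detector_forward(m, S, train = TRUE, keep_cache = TRUE)
  g <- pamscape:::detector_backward(m, fw, fw$p - y)
  loss <- function(model) {
    p <- pamscape:::detector_forward(model, S)$p
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  eps <- 1e-5
  for (nm in pamscape:::model_param_names(m)) {
    P <- pamscape:::get_param(m, nm)
    G <- pamscape:::get_grad(g, nm)
    for (i in sample(length(P), min(3, length(P)))) {
      Pp <- P; Pp[i] <- Pp[i] + eps
      Pm <- P; Pm[i] <- Pm[i] - eps
      num <- (loss(pamscape:::set_param(m, nm, Pp)) -
                loss(pamscape:::set_param(m, nm, Pm))) / (2 * eps)
      expect_lt(abs(num - G[i]) / max(1e-6, abs(num) + abs(G[i])), 1e-4)
    }
  }
})

test_that("SE gate forced to one equals the network without SE", {
  m <- tiny_model()
  S <- matrix(stats::rnorm(80), 10, 8)
  # saturate the gate: zero bottleneck weights, huge bias -> sigmoid ~ 1
  m_sat <- m
  for (bi in seq_along(m_sat$blocks)) {
    m_sat$blocks[[bi]]$se_W2[] <- 0
    m_sat$blocks[[bi]]$se_b2[] <- 50
  }
  p_sat <- pamscape:::detector_forward(m_sat, S)$p
  p_off <- pamscape:::detector_forward(m_sat, S, force_se_identity = TRUE)$p
  expect_equal(p_sat, p_off, tolerance = 1e-10)
})

test_that("uniform attention equals mean pooling; single frame passthrough", {
  m <- tiny_model()
  S <- matrix(stats::rnorm(96), 12, 8)
  fw <- pamscape:::detector_forward(m, S, force_uniform_attention = TRUE,
                                    keep_cache = TRUE)
  u_mean <- rep(colMeans(fw$FeatM), m$cfg$attention_heads)
  expect_equal(fw$u, u_mean, tolerance = 1e-12)
  fw1 <- pamscape:::detector_forward(m, matrix(stats::rnorm(8), 1, 8),
                                     keep_cache = TRUE)
  expect_equal(as.vector(fw1$A), rep(1, m$cfg$attention_heads))
  expect_equal(fw1$u, rep(fw1$FeatM[1, ], m$cfg$attention_heads))
})

test_that("band-count mismatch raises a shape error", {
  m <- tiny_model()
  expect_error(score_spectrogram(m, matrix(0, 10, 9)), "shape error")
})

test_that("site-independent split honours whole sites and fractions", {
  clips <- lapply(1:130, function(i)
    list(site_id = sprintf("S%02d", ((i - 1) %% 13) + 1), label = "negative",
         clip_id = as.character(i)))
  sp <- split_site_independent(clips, seed = 3)
  site_of <- function(part) unique(vapply(part, `[[`, character(1), "site_id"))
  expect_length(site_of(sp$test), 3)       # 13 sites at ~3/13 -> 3 sites
  expect_length(site_of(sp$validation), 3)
  expect_length(site_of(sp$train), 7)
  all_sites <- c(site_of(sp$train), site_of(sp$validation), site_of(sp$test))
  expect_false(any(duplicated(all_sites)))
  # 3 sites, equal fractions -> one site each
  clips3 <- clips[1:3]
  sp3 <- split_site_independent(clips3, c(train = 1, validation = 1, test = 1),
                                seed = 1)
  expect_length(site_of(sp3$train), 1)
  expect_length(site_of(sp3$test), 1)
  # determinism
  sp_b <- split_site_independent(clips, seed = 3)
  expect_identical(sp$site_assignment, sp_b$site_assignment)
  expect_error(split_site_independent(clips[1:2]), "3 distinct sites")
})

test_that("evaluate reproduces hand-computed confusion metrics", {
  # TP=3 FN=1 FP=2 TN=4 -> UAR = (0.75 + 4/6)/2
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  scores <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  ev <- evaluate(labels, scores)
  expect_equal(unname(ev$confusion), c(3, 1, 2, 4))
  expect_equal(ev$uar, (0.75 + 4 / 6) / 2, tolerance = 1e-12)
  # perfect predictions on a balanced set
  evp <- evaluate(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(evp$uar, 1)
  expect_equal(evp$f1, 1)
  expect_error(evaluate(numeric(0), numeric(0)), "empty")
})

test_that("training behaviour: loss decreases, errors and epoch-0 flag", {
  fx <- trained_easy_model()
  log <- fx$model$log
  # smoothed monotone decrease of training BCE
  sm <- stats::filter(log$train_loss, rep(1 / 2, 2), sides = 1)
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  expect_true(fx$model$trained)
  expect_true(fx$model$best_epoch >= 1)
  pos_only <- Filter(function(cl) cl$label == "positive", easy_clipset())
  m <- tiny_model()
  expect_error(train_detector(m, pos_only, pos_only, desk_ml_config()),
               "single class")
  cfg0 <- detector_config(conv_channels = c(4), epochs = 0)
  m0 <- build_model(cfg0, n_mels = 32)
  expect_warning(
    m0 <- train_detector(m0, easy_clipset()[c(1, 2, 61, 62)],
                         easy_clipset()[c(1, 2, 61, 62)], desk_ml_config()),
    "untrained")
  expect_false(m0$trained)
})

test_that("prediction sets are nested in the threshold", {
  fx <- trained_easy_model()
  test_clips <- fx$split$test
  d0 <- predict_detections(fx$model, test_clips, threshold = 0)
  d3 <- predict_detections(fx$model, test_clips, threshold = 0.3)
  d5 <- predict_detections(fx$model, test_clips, threshold = 0.5)
  expect_equal(nrow(d0), length(test_clips))   # threshold 0 emits everything
  expect_true(all(d5$file %in% d3$file))
  expect_true(all(d3$file %in% d0$file))
  expect_true(all(d5$confidence >= 0.5))
  expect_error(predict_detections(fx$model, test_clips, threshold = 1.0001),
               "threshold")
})

test_that("export_positives writes bijective CSV/clips and round-trips audio", {
  audio_dir <- tempfile("audio")
  dir.create(audio_dir)
  rate <- 2000
  w <- synth_background(10, rate, list(pink = list(rms = 0.02)), seed = 1)
  write_wav(w, file.path(audio_dir, "rec.wav"))
  det <- data.frame(detection_id = sprintf("det%05d", 1:5), site_id = "S001",
                    file = "rec.wav", start_s = 0:4, end_s = 1:5,
                    confidence = 0.9, review_status = "unreviewed")
  out_dir <- tempfile("out")
  csv <- export_positives(det, audio_dir, out_dir)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 5)
  clips <- list.files(file.path(out_dir, "clips"))
  expect_setequal(clips, tab$clip_file)
  # clip re-read is sample-identical to the source window
  wsrc <- read_wav(file.path(audio_dir, "rec.wav"))
  wclip <- read_wav(file.path(out_dir, "clips", "det00002.wav"))
  expect_identical(wclip$samples,
                   wsrc$samples[(1 * rate + 1):(2 * rate)])
  # zero detections -> empty CSV with header, empty folder
  out0 <- tempfile("out0")
  csv0 <- export_positives(det[0, ], audio_dir, out0)
  expect_equal(nrow(utils::read.csv(csv0)), 0)
  expect_length(list.files(file.path(out0, "clips")), 0)
  det_bad <- det; det_bad$file <- "missing.wav"
  expect_error(export_positives(det_bad, audio_dir, tempfile()),
               "missing.wav")
})
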