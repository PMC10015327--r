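#' Convolutional whinny detector
#'
#' A compact convolutional network over log-Mel spectrograms with, after
#' each convolutional layer, a squeeze-and-excitation (SE) recalibration
#' (global-average squeeze, bottleneck of width channels/reduction, sigmoid
#' gate multiplied back onto the channels), and a multi-head attention
#' pooling that collapses the frame sequence into a single fixed vector
#' (per-head learned importance scores, softmax-normalized over frames,
#' heads concatenated) feeding a sigmoid classifier. Forward and backward
#' passes are implemented directly (im2col convolutions on BLAS), trained
#' with Adam on binary cross-entropy.
#'
#' @name whinny_detector
NULL

#' Detector configuration
#'
#' Desk-scale defaults: 4 conv blocks of 16/32/64/64 channels with 3x3
#' kernels and 2x2 max-pooling, SE reduction 4, 4 attention heads, dropout
#' 0.2, Adam at 1e-3, up to 30 epochs, batch size 16, decision threshold
#' 0.5.
#'
#' @param conv_channels channels per conv block.
#' @param se_reduction SE bottleneck reduction ratio (>= 1).
#' @param attention_heads number of attention heads (>= 1).
#' @param dropout dropout on the pooled vector during training.
#' @param threshold detection confidence threshold in [0, 1].
#' @param lr,epochs,batch_size Adam learning rate, epoch and batch settings.
#' @param seed run seed (initialization and shuffling).
#' @export
detector_config <- function(conv_channels = c(16, 32, 64, 64),
                            se_reduction = 4, attention_heads = 4,
                            dropout = 0.2, threshold = 0.5, lr = 1e-3,
                            epochs = 30, batch_size = 16, seed = 1) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (attention_heads < 1) stop("need >= 1 attention head")
  if (se_reduction < 1) stop("se_reduction must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  list(conv_channels = conv_channels, se_reduction = se_reduction,
       attention_heads = attention_heads, dropout = dropout,
       threshold = threshold, lr = lr, epochs = epochs,
       batch_size = batch_size, seed = seed)
}

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

#' Build an untrained detector model
#'
#' @param cfg a \code{\link{detector_config}}.
#' @param n_mels Mel-band count the model accepts (fixed at build time; a
#'   mismatched spectrogram raises a shape error).
#' @return list of class \code{"whinny_model"} holding the parameter arrays.
#' @export
build_model <- function(cfg = detector_config(), n_mels = 64) {
  set.seed(cfg$seed)
  blocks <- list()
  c_in <- 1L
  m <- n_mels
  for (c_out in cfg$conv_channels) {
    r <- max(1L, as.integer(round(c_out / cfg$se_reduction)))
    blocks[[length(blocks) + 1]] <- list(
      W = he_init(c(9 * c_in, c_out), 9 * c_in),
      b = numeric(c_out),
      se_W1 = he_init(c(r, c_out), c_out), se_b1 = numeric(r),
      se_W2 = he_init(c(c_out, r), r), se_b2 = numeric(c_out),
      c_in = c_in, c_out = c_out)
    c_in <- c_out
    if (m >= 2) m <- m %/% 2L
  }
  D <- m * c_in
  H <- cfg$attention_heads
  model <- structure(list(
    cfg = cfg, n_mels = n_mels, blocks = blocks, feat_dim = D,
    att_V = he_init(c(D, H), D), att_b = numeric(H),
    out_w = he_init(c(D * H, 1), D * H)[, 1], out_b = 0,
    trained = FALSE), class = "whinny_model")
  model
}

#' @export
print.whinny_model <- function(x, ...) {
  cat(sprintf(
    "whinny detector: %d conv blocks (%s ch) + SE(r=%g) + %d-head attention; %s\n",
    length(x$blocks), paste(x$cfg$conv_channels, collapse = "/"),
    x$cfg$se_reduction, x$cfg$attention_heads,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  out <- matrix(0, H * W, 9 * C)
  k <- 0L
  for (cc in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    out[, k] <- as.vector(xp[di + seq_len(H), dj + seq_len(W), cc])
  }
  out
}

col2im3 <- function(dpatch, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0L
  for (cc in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    dxp[di + seq_len(H), dj + seq_len(W), cc] <-
      dxp[di + seq_len(H), dj + seq_len(W), cc] + matrix(dpatch[, k], H, W)
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

maxpool2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  ph <- if (H >= 2) 2L else 1L
  pw <- if (W >= 2) 2L else 1L
  if (ph == 1 && pw == 1) return(list(y = x, which = NULL, dims = d, ph = 1, pw = 1))
  H2 <- H %/% ph; W2 <- W %/% pw
  cand <- array(-Inf, c(H2, W2, C, ph * pw))
  k <- 0L
  for (dj in seq_len(pw)) for (di in seq_len(ph)) {
    k <- k + 1L
    cand[, , , k] <- x[seq_len(H2) * ph - ph + di, seq_len(W2) * pw - pw + dj, ,
                       drop = FALSE]
  }
  y <- cand[, , , 1, drop = FALSE]
  wh <- array(1L, c(H2, W2, C))
  if (ph * pw > 1) for (k in 2:(ph * pw)) {
    ck <- cand[, , , k, drop = FALSE]
    upd <- ck > y
    y[upd] <- ck[upd]
    wh[upd[, , , 1]] <- k
  }
  list(y = array(y, c(H2, W2, C)), which = wh, dims = d, ph = ph, pw = pw)
}

maxpool2_back <- function(dy, pool) {
  if (pool$ph == 1 && pool$pw == 1) return(dy)
  d <- pool$dims; H <- d[1]; W <- d[2]; C <- d[3]
  ph <- pool$ph; pw <- pool$pw
  H2 <- dim(dy)[1]; W2 <- dim(dy)[2]
  dx <- array(0, d)
  k <- 0L
  for (dj in seq_len(pw)) for (di in seq_len(ph)) {
    k <- k + 1L
    mask <- pool$which == k
    slab <- array(0, c(H2, W2, C))
    slab[mask] <- dy[mask]
    dx[seq_len(H2) * ph - ph + di, seq_len(W2) * pw - pw + dj, ] <-
      dx[seq_len(H2) * ph - ph + di, seq_len(W2) * pw - pw + dj, , drop = FALSE] + slab
  }
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; S: frames x mels matrix. Returns p and, if keep_cache,
# everything needed for the backward pass.
detector_forward <- function(model, S, train = FALSE, keep_cache = FALSE,
                             force_se_identity = FALSE,
                             force_uniform_attention = FALSE,
                             drop_mask = NULL) {
  if (ncol(S) != model$n_mels)
    stop("shape error: spectrogram has ", ncol(S), " Mel bands, model expects ",
         model$n_mels)
  mu <- mean(S); sdv <- stats::sd(S)
  x <- array((S - mu) / (sdv + 1e-8), c(nrow(S), ncol(S), 1))
  caches <- list()
  for (bi in seq_along(model$blocks)) {
    bl <- model$blocks[[bi]]
    d <- dim(x); H <- d[1]; W <- d[2]
    patch <- im2col3(x)
    z <- patch %*% bl$W
    z <- sweep(z, 2, bl$b, "+")
    a <- array(pmax(z, 0), c(H, W, bl$c_out))
    # squeeze-and-excitation
    s <- apply(a, 3, mean)
    z1 <- pmax(bl$se_W1 %*% s + bl$se_b1, 0)
    g <- sigmoid(drop(bl$se_W2 %*% z1 + bl$se_b2))
    g_used <- if (force_se_identity) rep(1, bl$c_out) else g
    ase <- a * rep(g_used, each = H * W)
    pool <- maxpool2(ase)
    if (keep_cache)
      caches[[bi]] <- list(x_dims = d, patch = patch, z = z, a = a, s = s,
                           z1 = z1, g = g, g_used = g_used, pool = pool,
                           H = H, W = W)
    x <- pool$y
  }
  d <- dim(x)
  Tn <- d[1]
  FeatM <- matrix(x, Tn, d[2] * d[3])       # frames x features
  if (ncol(FeatM) != model$feat_dim)
    stop("shape error: pooled feature width ", ncol(FeatM),
         " does not match the model (", model$feat_dim, ")")
  Hh <- model$cfg$attention_heads
  E <- FeatM %*% model$att_V
  E <- sweep(E, 2, model$att_b, "+")
  A <- apply(E, 2, function(e) { e <- e - max(e); w <- exp(e); w / sum(w) })
  A <- matrix(A, Tn, Hh)
  if (force_uniform_attention) A <- matrix(1 / Tn, Tn, Hh)
  U <- crossprod(FeatM, A)                  # D x heads
  u <- as.vector(U)
  if (train && model$cfg$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- stats::rbinom(length(u), 1, 1 - model$cfg$dropout) /
        (1 - model$cfg$dropout)
    u_used <- u * drop_mask
  } else {
    drop_mask <- NULL
    u_used <- u
  }
  logit <- sum(u_used * model$out_w) + model$out_b
  p <- sigmoid(logit)
  if (!keep_cache) return(list(p = p))
  list(p = p, caches = caches, FeatM = FeatM, A = A, u = u, u_used = u_used,
       drop_mask = drop_mask, logit = logit, Tn = Tn, final_dims = d)
}

# backward pass for one sample; dlogit = dLoss/dlogit (p - y for BCE)
detector_backward <- function(model, fw, dlogit) {
  g <- list(blocks = vector("list", length(model$blocks)))
  du_used <- dlogit * model$out_w
  g$out_w <- dlogit * fw$u_used
  g$out_b <- dlogit
  du <- if (!is.null(fw$drop_mask)) du_used * fw$drop_mask else du_used
  D <- model$feat_dim
  Hh <- model$cfg$attention_heads
  dU <- matrix(du, D, Hh)
  dFeat <- matrix(0, fw$Tn, D)
  g$att_V <- matrix(0, D, Hh)
  g$att_b <- numeric(Hh)
  for (h in seq_len(Hh)) {
    duh <- dU[, h]
    alpha <- fw$A[, h]
    dalpha <- fw$FeatM %*% duh
    dFeat <- dFeat + alpha %*% t(duh)
    de <- alpha * (drop(dalpha) - sum(alpha * dalpha))
    g$att_V[, h] <- crossprod(fw$FeatM, de)
    g$att_b[h] <- sum(de)
    dFeat <- dFeat + de %*% t(model$att_V[, h])
  }
  dx <- array(dFeat, fw$final_dims)
  for (bi in rev(seq_along(model$blocks))) {
    bl <- model$blocks[[bi]]
    ca <- fw$caches[[bi]]
    dase <- maxpool2_back(dx, ca$pool)
    H <- ca$H; W <- ca$W; C <- bl$c_out
    da <- dase * rep(ca$g_used, each = H * W)
    dg <- vapply(seq_len(C), function(cc)
      sum(dase[, , cc] * ca$a[, , cc]), numeric(1))
    gb <- list()
    if (identical(ca$g_used, ca$g)) {
      dz2 <- dg * ca$g * (1 - ca$g)
      gb$se_W2 <- dz2 %*% t(ca$z1)
      gb$se_b2 <- dz2
      dz1 <- drop(t(bl$se_W2) %*% dz2) * (ca$z1 > 0)
      gb$se_W1 <- dz1 %*% t(ca$s)
      gb$se_b1 <- dz1
      ds <- drop(t(bl$se_W1) %*% dz1)
      da <- da + rep(ds / (H * W), each = H * W)
    } else {
      gb$se_W2 <- matrix(0, nrow(bl$se_W2), ncol(bl$se_W2))
      gb$se_b2 <- numeric(length(bl$se_b2))
      gb$se_W1 <- matrix(0, nrow(bl$se_W1), ncol(bl$se_W1))
      gb$se_b1 <- numeric(length(bl$se_b1))
    }
    dz <- matrix(da, H * W, C) * (matrix(ca$z > 0, H * W, C))
    gb$W <- crossprod(ca$patch, dz)
    gb$b <- colSums(dz)
    g$blocks[[bi]] <- gb
    if (bi > 1) {
      dpatch <- dz %*% t(bl$W)
      dx <- col2im3(dpatch, H, W, bl$c_in)
    }
  }
  g
}

model_param_names <- function(model) {
  nm <- c("att_V", "att_b", "out_w", "out_b")
  for (bi in seq_along(model$blocks))
    nm <- c(nm, paste0("blocks.", bi, ".",
                       c("W", "b", "se_W1", "se_b1", "se_W2", "se_b2")))
  nm
}

get_param <- function(model, name) {
  if (grepl("^blocks\\.", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    model$blocks[[as.integer(parts[2])]][[parts[3]]]
  } else model[[name]]
}

set_param <- function(model, name, value) {
  if (grepl("^blocks\\.", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    model$blocks[[as.integer(parts[2])]][[parts[3]]] <- value
  } else model[[name]] <- value
  model
}

get_grad <- function(g, name) {
  if (grepl("^blocks\\.", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    g$blocks[[as.integer(parts[2])]][[parts[3]]]
  } else g[[name]]
}

#' Score a single spectrogram
#'
#' @param model a (typically trained) \code{"whinny_model"}.
#' @param spec a \code{"spectrogram"} or a frames x mels matrix.
#' @param force_se_identity replace all SE gates by 1 (diagnostic).
#' @param force_uniform_attention replace attention by mean pooling
#'   (diagnostic).
#' @return confidence in [0, 1].
#' @export
score_spectrogram <- function(model, spec, force_se_identity = FALSE,
                              force_uniform_attention = FALSE) {
  S <- if (inherits(spec, "spectrogram")) spec$values else as.matrix(spec)
  detector_forward(model, S, force_se_identity = force_se_identity,
                   force_uniform_attention = force_uniform_attention)$p
}

#' Site-independent train/validation/test split
#'
#' Whole sites are assigned to partitions (largest-remainder rounding of the
#' fractions over the site count, each partition getting at least one site),
#' so no site contributes clips to two partitions.
#'
#' @param clips list of labelled clips (each with a \code{site_id}).
#' @param fractions named numeric \code{c(train=, validation=, test=)}.
#' @param seed shuffle seed.
#' @return list with \code{train}, \code{validation}, \code{test} clip lists
#'   and \code{site_assignment}.
#' @export
split_site_independent <- function(clips,
                                   fractions = c(train = 7 / 13,
                                                 validation = 3 / 13,
                                                 test = 3 / 13),
                                   seed = 1) {
  sites <- unique(vapply(clips, function(cl) cl$site_id, character(1)))
  if (length(sites) < 3) stop("need >= 3 distinct sites for three partitions")
  fr <- fractions / sum(fractions)
  n <- length(sites)
  counts <- pmax(1, floor(n * fr))
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  while (sum(counts) < n) {
    frac <- n * fr - counts
    counts[which.max(frac)] <- counts[which.max(frac)] + 1
  }
  set.seed(seed)
  shuffled <- sample(sites)
  assign <- rep(names(fractions), counts)
  site_assignment <- stats::setNames(assign, shuffled)
  pick <- function(part) {
    keep <- names(site_assignment)[site_assignment == part]
    Filter(function(cl) cl$site_id %in% keep, clips)
  }
  list(train = pick("train"), validation = pick("validation"),
       test = pick("test"), site_assignment = site_assignment)
}

clip_label01 <- function(cl) as.numeric(cl$label == "positive")

#' Spectrograms for a clip list
#'
#' @param clips labelled clips.
#' @param ml_config a \code{\link{logmel_config}}.
#' @return list of frames x mels matrices.
#' @export
clip_spectrograms <- function(clips, ml_config) {
  lapply(clips, function(cl) logmel(cl$waveform, ml_config)$values)
}

#' Train the detector
#'
#' Adam on binary cross-entropy with seeded shuffling; after each epoch the
#' validation unweighted average recall (UAR, at threshold 0.5) is logged
#' and the best checkpoint is kept (ties broken by the earlier epoch).
#' \code{epochs = 0} returns the untrained model, flagged.
#'
#' @param model a \code{"whinny_model"} from \code{\link{build_model}}.
#' @param train_clips,val_clips labelled clip lists; train must contain both
#'   classes.
#' @param ml_config log-Mel settings used to featurize the clips.
#' @return the model with trained parameters, \code{$log} (epoch, train
#'   loss, validation UAR) and \code{$best_epoch}.
#' @export
train_detector <- function(model, train_clips, val_clips,
                           ml_config = logmel_config(n_mels = 64)) {
  cfg <- model$cfg
  y <- vapply(train_clips, clip_label01, numeric(1))
  if (length(unique(y)) < 2) stop("training set contains a single class")
  if (cfg$epochs == 0) {
    model$trained <- FALSE
    model$log <- data.frame(epoch = integer(), train_loss = numeric(),
                            val_uar = numeric())
    warning("epochs = 0: returning the untrained model")
    return(model)
  }
  Xtr <- clip_spectrograms(train_clips, ml_config)
  Xva <- clip_spectrograms(val_clips, ml_config)
  yva <- vapply(val_clips, clip_label01, numeric(1))
  nms <- model_param_names(model)
  mom <- stats::setNames(lapply(nms, function(nm) get_param(model, nm) * 0), nms)
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tstep <- 0
  set.seed(cfg$seed)
  best_uar <- -Inf; best_params <- NULL; best_epoch <- NA_integer_
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_uar = numeric())
  n <- length(Xtr)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      bidx <- idx[start:min(start + cfg$batch_size - 1, n)]
      acc <- NULL
      bl <- 0
      for (i in bidx) {
        fw <- detector_forward(model, Xtr[[i]], train = TRUE, keep_cache = TRUE)
        p <- min(max(fw$p, 1e-12), 1 - 1e-12)
        bl <- bl - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
        g <- detector_backward(model, fw, fw$p - y[i])
        if (is.null(acc)) {
          acc <- stats::setNames(lapply(nms, get_grad, g = g), nms)
        } else {
          for (nm in nms) acc[[nm]] <- acc[[nm]] + get_grad(g, nm)
        }
      }
      nb <- length(bidx)
      losses <- c(losses, bl / nb)
      tstep <- tstep + 1
      for (nm in nms) {
        gr <- acc[[nm]] / nb
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr^2
        mhat <- mom[[nm]] / (1 - b1^tstep)
        vhat <- vel[[nm]] / (1 - b2^tstep)
        model <- set_param(model, nm,
                           get_param(model, nm) - cfg$lr * mhat / (sqrt(vhat) + eps))
      }
    }
    pv <- vapply(Xva, function(Sx) detector_forward(model, Sx)$p, numeric(1))
    ev <- evaluate(yva, pv, threshold = 0.5)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                 val_uar = ev$uar))
    if (ev$uar > best_uar + 1e-12) {   # strict: ties keep the earlier epoch
      best_uar <- ev$uar
      best_params <- stats::setNames(lapply(nms, get_param, model = model), nms)
      best_epoch <- ep
    }
  }
  for (nm in nms) model <- set_param(model, nm, best_params[[nm]])
  model$trained <- TRUE
  model$log <- log
  model$best_epoch <- best_epoch
  model$ml_config <- ml_config
  model
}

#' Thresholded window inference
#'
#' Scores each analysis window and emits exactly those with confidence at or
#' above the threshold; lowering the threshold can only add detections
#' (nested detection sets).
#'
#' @param model trained \code{"whinny_model"} (with \code{$ml_config}).
#' @param windows list from \code{\link{window_stream}}, or labelled clips.
#' @param threshold confidence threshold in [0, 1].
#' @param site_id recorded on the detections.
#' @return data frame of detections: detection_id, site_id, file, start_s,
#'   end_s, confidence, review_status ("unreviewed").
#' @export
predict_detections <- function(model, windows, threshold = 0.5,
                               site_id = "S001") {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ml <- model$ml_config
  if (is.null(ml)) ml <- logmel_config(n_mels = model$n_mels)
  rows <- lapply(seq_along(windows), function(i) {
    wn <- windows[[i]]
    if (!is.null(wn$waveform)) {   # labelled clip
      S <- logmel(wn$waveform, ml)$values
      start <- 0; end <- wav_duration(wn$waveform)
      fl <- wn$clip_id
    } else {
      S <- logmel(waveform(wn$samples, wn$rate), ml)$values
      start <- wn$start; end <- wn$end; fl <- wn$file
    }
    conf <- detector_forward(model, S)$p
    data.frame(file = fl, start_s = start, end_s = end, confidence = conf)
  })
  df <- do.call(rbind, rows)
  keep <- df$confidence >= threshold
  out <- df[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    out$detection_id <- sprintf("det%05d", seq_len(nrow(out)))
    out$site_id <- site_id
    out$review_status <- "unreviewed"
  } else {
    out$detection_id <- character(0)
    out$site_id <- character(0)
    out$review_status <- character(0)
  }
  rownames(out) <- NULL
  out[, c("detection_id", "site_id", "file", "start_s", "end_s",
          "confidence", "review_status")]
}

#' Detector evaluation metrics
#'
#' Confusion counts at a threshold plus the unweighted-average metrics: UAR
#' (mean of positive and negative recall), unweighted-average precision, and
#' F1 as the harmonic mean of those two averages (per-class F1 is also
#' reported).
#'
#' @param labels binary truth vector (1 = positive).
#' @param scores confidences in [0, 1] (or already-binary predictions).
#' @param threshold decision threshold.
#' @return list of class \code{"eval_report"}.
#' @export
evaluate <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  fp <- sum(pred == 1 & labels == 0); tn <- sum(pred == 0 & labels == 0)
  recall_pos <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  recall_neg <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  uar <- mean(c(recall_pos, recall_neg), na.rm = TRUE)
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  precision <- mean(c(prec_pos, prec_neg), na.rm = TRUE)
  f1 <- harmonic_f1(precision, uar)
  f1_pos <- harmonic_f1(prec_pos, recall_pos)
  structure(list(recall_pos = recall_pos, recall_neg = recall_neg, uar = uar,
                 precision_pos = prec_pos, precision_neg = prec_neg,
                 precision = precision, f1 = f1, f1_pos = f1_pos,
                 confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
                 threshold = threshold),
            class = "eval_report")
}

#' Harmonic mean of precision and recall
#' @param precision,recall values in [0, 1].
#' @export
harmonic_f1 <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0)
    return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("UAR %.3f (recall + %.3f / - %.3f), precision %.3f, F1 %.3f\n",
              x$uar, x$recall_pos, x$recall_neg, x$precision, x$f1))
  cat("confusion:", paste(names(x$confusion), x$confusion, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#' @param labels binary truth.
#' @param scores confidences.
#' @export
auroc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Export positive detections as CSV plus clipped audio
#'
#' One CSV row and one clipped WAV (duration = the analysis window) per
#' detection, with bijective CSV-to-clip naming.
#'
#' @param detections detection data frame from
#'   \code{\link{predict_detections}}.
#' @param audio_dir directory holding the source WAV files named in the
#'   detections.
#' @param out_dir output directory (created); clips land in
#'   \code{out_dir/clips}.
#' @return path of the written CSV.
#' @export
export_positives <- function(detections, audio_dir, out_dir) {
  dir.create(file.path(out_dir, "clips"), showWarnings = FALSE, recursive = TRUE)
  det <- detections
  det$clip_file <- if (nrow(det) > 0)
    paste0(det$detection_id, ".wav") else character(0)
  missing <- unique(det$file[!file.exists(file.path(audio_dir, det$file))])
  if (length(missing) > 0)
    stop("missing source audio: ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(det))) {
    w <- read_wav(file.path(audio_dir, det$file[i]))
    i0 <- round(det$start_s[i] * w$rate) + 1
    i1 <- min(round(det$end_s[i] * w$rate), length(w$samples))
    write_wav(waveform(w$samples[i0:i1], w$rate),
              file.path(out_dir, "clips", det$clip_file[i]))
  }
  csv <- file.path(out_dir, "positives.csv")
  utils::write.csv(det, csv, row.names = FALSE)
  csv
}
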