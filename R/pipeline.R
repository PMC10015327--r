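#' End-to-end pipeline orchestration
#'
#' Runs the synthetic-to-inference flow with a single reproducible config:
#' (audio path) clip set -> site-independent split -> detector training ->
#' thresholded inference -> simulated review -> detection histories;
#' (landscape path) sites -> layers -> buffer covariates -> occurrence truth
#' -> scale-of-effect screen -> occurrence GLMs with spatial diagnostics ->
#' variance partitioning and the null occupancy model. Stage toggles let the
#' statistics run without the (slower) audio stage; the effective config is
#' persisted next to the outputs.
#'
#' @name cli_pipeline
NULL

#' Default run configuration
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir output directory.
#' @param run_audio include the audio/detector stage (slow).
#' @param n_sites,region landscape network size.
#' @param audio list of audio-stage sizes (clip counts, epochs, rate).
#' @return nested list of stage parameter blocks.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("pamscape"),
                           run_audio = FALSE, n_sites = 341,
                           region = c(22000, 22000),
                           audio = list(n_pos = 40, n_neg = 40, n_sites = 6,
                                        rate = 4000, n_mels = 32,
                                        epochs = 6, channels = c(8, 16))) {
  list(seed = seed, out_dir = out_dir,
       stages = list(audio = run_audio, landscape = TRUE, stats = TRUE),
       landscape = list(n_sites = n_sites, region = region, min_dist = 500,
                        cell = 50, margin = 1100),
       radii = list(forest = c(100, 200, 500, 1000),
                    roads = c(100, 200, 500, 1000)),
       truth = list(forest_threshold = 80, forest_slope = 0.25,
                    spatial_sd = 1.2, spatial_range = 3000, p_daily = 0.68),
       audio = audio)
}

#' Read a config file (JSON, or flat "key: value" text)
#'
#' @param path config file; JSON preserves nesting, the flat key-value form
#'   overrides top-level scalar fields of the defaults.
#' @return config list merged over \code{\link{default_config}}.
#' @export
read_config <- function(path) {
  base <- default_config()
  txt <- readLines(path, warn = FALSE)
  is_json <- any(grepl("^\\s*\\{", txt))
  if (is_json) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    kv <- Filter(function(l) grepl(":", l) && !grepl("^\\s*#", l), txt)
    user <- list()
    for (l in kv) {
      k <- trimws(sub(":.*$", "", l))
      v <- trimws(sub("^[^:]*:", "", l))
      vn <- suppressWarnings(as.numeric(v))
      user[[k]] <- if (!is.na(vn)) vn else v
    }
  }
  utils::modifyList(base, user)
}

#' Run the full pipeline
#'
#' @param cfg config list (see \code{\link{default_config}}).
#' @return list of class \code{"pipeline_report"} aggregating stage outputs;
#'   CSV artifacts are written under \code{cfg$out_dir}.
#' @export
run_pipeline <- function(cfg = default_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- list(config = cfg, stages = character(0))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[pamscape] stage %-12s %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    report$stages <<- c(report$stages, name)
    val
  }

  if (isTRUE(cfg$stages$audio)) {
    au <- cfg$audio
    clips <- stage("synth-audio", make_clipset(
      n_pos = au$n_pos, n_neg = au$n_neg, hard_negative_fraction = 0,
      n_sites = au$n_sites, rate = au$rate, snr_range = c(15, 30),
      seed = cfg$seed))
    ml <- logmel_config(n_mels = au$n_mels, fmax = au$rate / 2 - 1)
    sp <- stage("split", split_site_independent(clips, seed = cfg$seed))
    model <- build_model(detector_config(conv_channels = au$channels,
                                         epochs = au$epochs, seed = cfg$seed),
                         n_mels = au$n_mels)
    model <- stage("train", train_detector(model, sp$train, sp$validation, ml))
    det <- stage("detect", predict_detections(model, sp$test, threshold = 0.5))
    labs <- vapply(sp$test, clip_label01, numeric(1))
    scores <- vapply(sp$test, function(cl)
      score_spectrogram(model, logmel(cl$waveform, ml)), numeric(1))
    report$detector <- list(eval = evaluate(labs, scores),
                            n_detections = nrow(det),
                            best_epoch = model$best_epoch)
    utils::write.csv(model$log, file.path(cfg$out_dir, "training_log.csv"),
                     row.names = FALSE)
  }

  ls_cfg <- cfg$landscape
  sites <- stage("synth-landscape", synth_sites(
    ls_cfg$n_sites, region = ls_cfg$region, min_dist = ls_cfg$min_dist,
    seed = cfg$seed))
  layers <- synth_layers(sites, cell = ls_cfg$cell, margin = ls_cfg$margin,
                         seed = cfg$seed + 1)
  tab <- stage("metrics", metrics_table(sites, layers,
                                        radii_forest = cfg$radii$forest,
                                        radii_roads = cfg$radii$roads))
  truth <- occurrence_truth(forest_threshold = cfg$truth$forest_threshold,
                            forest_slope = cfg$truth$forest_slope,
                            spatial_sd = cfg$truth$spatial_sd,
                            spatial_range = cfg$truth$spatial_range,
                            p_daily = cfg$truth$p_daily)
  occ <- synth_occurrence(sites, tab, truth, seed = cfg$seed + 2)
  tab$occurrence <- occ$occurrence
  write_metrics_table(tab, file.path(cfg$out_dir, "site_covariates.csv"))

  if (isTRUE(cfg$stages$stats)) {
    forest_cols <- paste0("forest_cover_", cfg$radii$forest)
    prof <- stage("scale", profile_scales(
      tab$occurrence, as.matrix(as.data.frame(tab)[forest_cols]),
      radii = cfg$radii$forest))
    utils::write.csv(prof$profile, file.path(cfg$out_dir, "scale_profile.csv"),
                     row.names = FALSE)
    sel <- prof$selected_radius
    x <- tab[[paste0("forest_cover_", sel)]]
    ac <- autocovariate(tab$occurrence, cbind(sites$x, sites$y))
    # quadratic cover term only when the covariate supports it
    cover_X <- if (length(unique(x)) > 2) stats::poly(x, 2) else cbind(x)
    X <- cbind(1, cover_X, autocov = ac)
    colnames(X) <- c("(Intercept)", paste0("cover", seq_len(ncol(cover_X))),
                     "autocov")
    fit <- stage("fit", {
      f <- fit_logistic(X, tab$occurrence)
      if (f$separation) f <- fit_firth(X, tab$occurrence)
      f
    })
    wts <- spatial_weights(cbind(sites$x, sites$y))
    report$moran <- stage("spatial", morans_i(fit$residuals, wts))
    utils::write.csv(summary_table(fit),
                     file.path(cfg$out_dir, "model_summary.csv"),
                     row.names = FALSE)
    preds <- list(
      forest = as.matrix(cover_X),
      secondary_roads = tab[[paste0("secondary_road_density_",
                                    max(cfg$radii$roads))]],
      buildings = tab[[paste0("building_area_", max(cfg$radii$roads))]],
      autocov = ac)
    part <- stage("partition", hier_partition(tab$occurrence, preds))
    utils::write.csv(part$table, file.path(cfg$out_dir, "partition.csv"),
                     row.names = FALSE)
    occ_fit <- stage("occupancy", null_occupancy_mle(occ$histories))
    report$scale <- prof
    report$fit <- fit
    report$partition <- part
    report$occupancy <- occ_fit
    report$naive_occupancy <- naive_occupancy(tab$occurrence)
    report$tipping <- tipping_point(tab$occurrence, x, "presence-above")
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pamscape pipeline report; stages run:",
      paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$detector))
    cat(sprintf("detector: UAR %.3f on the test sites\n", x$detector$eval$uar))
  if (!is.null(x$scale))
    cat(sprintf("scale of effect: %g m\n", x$scale$selected_radius))
  if (!is.null(x$moran))
    cat(sprintf("Moran's I on residuals: %.4f (p = %.3g)\n",
                x$moran$I, x$moran$p))
  if (!is.null(x$occupancy))
    cat(sprintf("null occupancy: psi %.3f, p %.3f (naive %.3f)\n",
                x$occupancy$psi, x$occupancy$p, x$naive_occupancy))
  invisible(x)
}

#' Command-line entry point
#'
#' Dispatches the subcommands (pipeline, synth-landscape, metrics, scale,
#' fit, spatial, partition, occupancy, synth-audio, train, detect, review,
#' histories) used by the \code{inst/cli/pamscape} wrapper; each accepts
#' \code{--seed}, \code{--config} and \code{--out}.
#'
#' @param args command-line arguments (default
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return exit status, invisibly (0 on success).
#' @export
pamscape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: pamscape <subcommand> [--seed N] [--config FILE] [--out DIR]\n")
    cat("subcommands: pipeline stats-only full\n")
    return(invisible(1L))
  }
  sub <- args[1]
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(getopt("--seed", "1"))
  out <- getopt("--out", tempfile("pamscape"))
  cfg_path <- getopt("--config", NA)
  cfg <- if (!is.na(cfg_path)) read_config(cfg_path) else default_config()
  cfg$seed <- seed
  cfg$out_dir <- out
  if (sub %in% c("pipeline", "stats-only")) {
    cfg$stages$audio <- FALSE
  } else if (sub == "full") {
    cfg$stages$audio <- TRUE
  } else {
    cat("unknown subcommand: ", sub, "\n")
    return(invisible(1L))
  }
  rep <- run_pipeline(cfg)
  print(rep)
  invisible(0L)
}
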