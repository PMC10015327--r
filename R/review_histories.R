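#' Detection review and detection-history coding
#'
#' Bookkeeping for the semi-automated workflow: every detector positive is
#' verified by a reviewer (or, in tests, by the synthetic-event manifest),
#' true positives are tallied per site and day, and 7-day binary detection
#' histories and site occurrence are coded from the tallies.
#'
#' @name review_histories
NULL

#' Apply review verdicts to detections
#'
#' @param detections data frame with at least \code{detection_id},
#'   \code{site_id} and \code{day} columns (day an integer 1..7).
#' @param decisions data frame with \code{detection_id} and \code{verdict}
#'   (\code{"true_positive"} or \code{"false_positive"}); every detection
#'   must be covered exactly once.
#' @return list with \code{verified} (detections joined with verdicts) and
#'   \code{daily_counts}, a site x day matrix of true-positive counts.
#' @export
apply_reviews <- function(detections, decisions) {
  if (nrow(detections) == 0) {
    return(list(verified = detections,
                daily_counts = matrix(0, 0, 7,
                                      dimnames = list(NULL, paste0("d", 1:7)))))
  }
  if (anyDuplicated(decisions$detection_id))
    stop("multiple verdicts for one detection")
  idx <- match(detections$detection_id, decisions$detection_id)
  if (anyNA(idx))
    stop("unreviewed detections present: ",
         paste(utils::head(detections$detection_id[is.na(idx)], 5), collapse = ", "))
  verdict <- decisions$verdict[idx]
  if (!all(verdict %in% c("true_positive", "false_positive")))
    stop("verdicts must be true_positive or false_positive")
  detections$review_status <- verdict
  sites <- sort(unique(detections$site_id))
  days <- sort(unique(c(detections$day, 1:7)))
  counts <- matrix(0L, length(sites), length(days),
                   dimnames = list(as.character(sites), paste0("d", days)))
  tp <- detections[verdict == "true_positive", , drop = FALSE]
  if (nrow(tp) > 0) {
    t2 <- table(factor(tp$site_id, levels = sites),
                factor(tp$day, levels = days))
    counts[] <- as.integer(t2)
  }
  list(verified = detections, daily_counts = counts)
}

#' Code a 7-day detection history from daily true-positive counts
#'
#' Sites with fewer than 7 recording days are excluded (mirroring the
#' recorder-malfunction rule), not coded.
#'
#' @param counts numeric vector of daily true-positive counts for one site.
#' @param site_id identifier carried through.
#' @param n_days_required required number of days (default 7).
#' @return list of class \code{"detection_history"} with \code{site_id},
#'   \code{days} (binary 7-vector) and \code{excluded = FALSE}; or with
#'   \code{excluded = TRUE} and no coding when days are missing.
#' @export
code_history <- function(counts, site_id = NA, n_days_required = 7) {
  if (length(counts) < n_days_required) {
    return(structure(list(site_id = site_id, days = NULL, excluded = TRUE,
                          n_days = length(counts)),
                     class = "detection_history"))
  }
  if (length(counts) > n_days_required)
    stop("more than ", n_days_required, " days of counts")
  if (any(counts < 0)) stop("negative counts")
  structure(list(site_id = site_id, days = as.integer(counts > 0),
                 excluded = FALSE, n_days = length(counts)),
            class = "detection_history")
}

#' Site occurrence from a detection history
#'
#' Presence on one or more days codes the site 1; absence on all days 0.
#'
#' @param h a \code{"detection_history"} (not excluded).
#' @return list with \code{site_id} and binary \code{occurrence}.
#' @export
site_occurrence <- function(h) {
  if (isTRUE(h$excluded)) stop("site was excluded (insufficient days)")
  list(site_id = h$site_id, occurrence = as.integer(max(h$days)))
}

#' Naive occupancy
#'
#' The fraction of analysed sites with at least one verified detection,
#' uncorrected for imperfect detection.
#'
#' @param occurrences binary vector of site occurrence.
#' @return proportion in [0, 1].
#' @export
naive_occupancy <- function(occurrences) {
  if (length(occurrences) == 0) stop("no sites")
  if (!all(occurrences %in% c(0, 1))) stop("occurrences must be binary")
  mean(occurrences)
}

#' Simulated review verdicts from a synthetic event manifest
#'
#' Stands in for the human verification pass in unattended runs: a detection
#' is a true positive iff its window overlaps a whinny event of the manifest
#' in the same file.
#'
#' @param detections data frame with \code{detection_id}, \code{file},
#'   \code{start_s}, \code{end_s}.
#' @param manifest event manifest data frame (\code{file}, \code{onset_s},
#'   \code{duration_s}, \code{kind}).
#' @param reviewer label recorded on the decisions.
#' @return decisions data frame consumable by \code{\link{apply_reviews}}.
#' @export
simulate_reviews <- function(detections, manifest, reviewer = "manifest") {
  ev <- manifest[manifest$kind == "whinny", , drop = FALSE]
  verdict <- vapply(seq_len(nrow(detections)), function(i) {
    dt <- detections[i, ]
    hit <- any(ev$file == dt$file &
                 ev$onset_s < dt$end_s &
                 ev$onset_s + ev$duration_s > dt$start_s)
    if (hit) "true_positive" else "false_positive"
  }, character(1))
  data.frame(detection_id = detections$detection_id, verdict = verdict,
             reviewer = reviewer, timestamp = rep(Sys.time(), nrow(detections)))
}

#' Write / read detection-history tables
#'
#' Histories CSV uses columns \code{site_id, d1..d7, occurrence}.
#'
#' @param histories list of \code{"detection_history"} objects (excluded
#'   sites are dropped with a message).
#' @param path CSV path.
#' @return the written data frame, invisibly.
#' @export
write_histories <- function(histories, path) {
  keep <- Filter(function(h) !isTRUE(h$excluded), histories)
  df <- do.call(rbind, lapply(keep, function(h) {
    row <- as.data.frame(as.list(stats::setNames(h$days, paste0("d", 1:7))))
    cbind(data.frame(site_id = h$site_id), row,
          data.frame(occurrence = site_occurrence(h)$occurrence))
  }))
  if (is.null(df))
    df <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 9)),
                          c("site_id", paste0("d", 1:7), "occurrence"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
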