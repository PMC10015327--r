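#' Hierarchical variance partitioning and the null occupancy model
#'
#' All-subsets (Chevan-Sutherland) decomposition of logistic-model
#' goodness-of-fit into independent and joint contributions per predictor,
#' and the constant-psi constant-p occupancy model that separates daily
#' detection probability from site occupancy in 7-day detection histories.
#'
#' @name variance_partition_occupancy
NULL

#' Hierarchical partitioning of logistic goodness-of-fit
#'
#' Fits all \eqn{2^k} predictor subsets and averages, over hierarchy levels,
#' the goodness-of-fit gain each predictor brings to subsets lacking it
#' (equivalently its Shapley value). The independent contributions sum
#' exactly to the full-model goodness-of-fit; the joint contribution is the
#' marginal single-predictor fit minus the independent part.
#'
#' @param y binary response, both classes present.
#' @param predictors named list mapping each predictor name to a numeric
#'   column or matrix of columns (a dummy-coded factor enters as one block),
#'   or a data frame / matrix whose columns are single-column predictors.
#' @param gof goodness-of-fit function taking an \code{"occfit"}; defaults
#'   to McFadden pseudo-R-squared, matching the scale-of-effect screen.
#' @param fitter \code{"auto"} (ML, falling back to bias-reduced whenever any
#'   subset separates — the whole hierarchy is then refitted bias-reduced for
#'   comparability), \code{"ml"} or \code{"firth"}.
#' @return list of class \code{"partition_result"} with the per-predictor
#'   table (independent, joint, independent as percent of total) and the
#'   full-model goodness-of-fit.
#' @export
hier_partition <- function(y, predictors, gof = pseudo_r2,
                           fitter = c("auto", "ml", "firth")) {
  fitter <- match.arg(fitter)
  if (is.matrix(predictors) || is.data.frame(predictors)) {
    predictors <- as.data.frame(predictors)
    predictors <- stats::setNames(
      lapply(predictors, function(col) as.matrix(col)), names(predictors))
  }
  k <- length(predictors)
  if (k < 1) stop("need at least one predictor")
  if (k > 6) stop("refusing k > 6 predictors (2^k subset fits)")
  if (length(unique(y)) < 2) stop("y contains a single class")
  nms <- names(predictors)
  if (is.null(nms) || any(nms == "")) stop("predictors must be named")
  blocks <- lapply(predictors, as.matrix)

  fit_subset <- function(idx, use_firth) {
    if (length(idx) == 0) {
      X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    } else {
      X <- cbind(1, do.call(cbind, blocks[idx]))
      colnames(X) <- c("(Intercept)", paste0("c", seq_len(ncol(X) - 1)))
      # drop aliased columns (e.g. duplicated predictors) before fitting
      qrX <- qr(X)
      if (qrX$rank < ncol(X))
        X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
    if (use_firth) fit_firth(X, y) else fit_logistic(X, y)
  }

  subsets <- lapply(0:(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  run_all <- function(use_firth) lapply(subsets, fit_subset, use_firth = use_firth)
  use_firth <- fitter == "firth"
  fits <- run_all(use_firth)
  if (fitter == "auto" &&
      any(vapply(fits, function(f) isTRUE(f$separation), logical(1)))) {
    use_firth <- TRUE
    fits <- run_all(TRUE)
  }
  g <- vapply(fits, gof, numeric(1))
  key <- vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1))
  gof_of <- function(s) g[match(paste(sort(s), collapse = ","), key)]

  indep <- stats::setNames(numeric(k), nms)
  for (xi in seq_len(k)) {
    others <- setdiff(seq_len(k), xi)
    # Shapley weights: |S|! (k-|S|-1)! / k! over subsets S not containing xi
    total <- 0
    for (m in 0:(2^length(others) - 1)) {
      s <- others[which(bitwAnd(m, 2^(seq_along(others) - 1)) > 0)]
      wgt <- factorial(length(s)) * factorial(k - length(s) - 1) / factorial(k)
      total <- total + wgt * (gof_of(c(s, xi)) - gof_of(s))
    }
    indep[xi] <- total
  }
  marginal <- vapply(seq_len(k), function(xi) gof_of(xi), numeric(1))
  full <- gof_of(seq_len(k))
  tab <- data.frame(predictor = nms, independent = unname(indep),
                    joint = unname(marginal - indep),
                    marginal = unname(marginal),
                    pct_of_total = unname(100 * indep / sum(indep)),
                    row.names = NULL)
  structure(list(table = tab, total_gof = full,
                 method = if (use_firth) "bias-reduced" else "ML"),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Hierarchical partitioning (%s fits), total gof = %.4f\n",
              x$method, x$total_gof))
  print(transform(x$table, independent = round(independent, 4),
                  joint = round(joint, 4), marginal = round(marginal, 4),
                  pct_of_total = round(pct_of_total, 1)), row.names = FALSE)
  invisible(x)
}

occupancy_nll <- function(par, d, J) {
  psi <- stats::plogis(par[1]); p <- stats::plogis(par[2])
  det_ll <- sum(log(psi) + d[d > 0] * log(p) + (J - d[d > 0]) * log(1 - p))
  nd <- sum(d == 0)
  nd_ll <- nd * log(psi * (1 - p)^J + (1 - psi))
  -(det_ll + nd_ll)
}

#' Null occupancy model MLE
#'
#' Maximum likelihood for the constant-occupancy constant-detection model on
#' J-occasion detection histories: sites with \eqn{d_i > 0} detections
#' contribute \eqn{\psi p^{d_i} (1-p)^{J - d_i}}, undetected sites contribute
#' \eqn{\psi (1-p)^J + (1-\psi)}. Optimized on the logit scale; standard
#' errors by the delta method from the numerical Hessian.
#'
#' @param histories matrix of 0/1 with one row per site and J columns, or a
#'   list of binary J-vectors.
#' @param J number of occasions (default 7; inferred from the input).
#' @return list of class \code{"occupancy_fit"}: \code{psi}, \code{p}, their
#'   standard errors, the maximized log-likelihood and the naive occupancy.
#' @export
null_occupancy_mle <- function(histories, J = NULL) {
  H <- if (is.list(histories)) do.call(rbind, histories) else as.matrix(histories)
  if (is.null(J)) J <- ncol(H)
  if (!all(H %in% c(0, 1))) stop("histories must be binary")
  d <- rowSums(H)
  if (all(d == 0)) stop("all-zero histories: occupancy unidentifiable")
  naive <- mean(d > 0)
  start <- c(stats::qlogis(min(max(naive, 0.05), 0.95)), 0)
  opt <- stats::optim(start, occupancy_nll, d = d, J = J, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500, reltol = 1e-12))
  psi <- stats::plogis(opt$par[1]); p <- stats::plogis(opt$par[2])
  se_logit <- tryCatch(sqrt(diag(solve(opt$hessian))),
                       error = function(e) c(NA_real_, NA_real_))
  structure(list(psi = psi, p = p,
                 se_psi = se_logit[1] * psi * (1 - psi),
                 se_p = se_logit[2] * p * (1 - p),
                 loglik = -opt$value, naive_occupancy = naive,
                 n_sites = nrow(H), J = J,
                 converged = opt$convergence == 0),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Null occupancy model: psi = %.3f (SE %.3f), p = %.3f (SE %.3f)\n",
              x$psi, x$se_psi, x$p, x$se_p))
  cat(sprintf("naive occupancy %.3f over %d sites x %d days; logLik %.3f\n",
              x$naive_occupancy, x$n_sites, x$J, x$loglik))
  invisible(x)
}

#' Simulate detection histories under the null occupancy model
#'
#' Each site is occupied with probability \code{psi}; occupied sites get J
#' i.i.d. Bernoulli(\code{p}) daily detections, unoccupied sites all-zero
#' histories.
#'
#' @param n_sites number of sites.
#' @param psi occupancy probability.
#' @param p daily detection probability given occupancy.
#' @param J occasions per site (default 7).
#' @param seed optional RNG seed.
#' @return list with the history matrix and the latent occupancy vector.
#' @export
simulate_histories <- function(n_sites, psi, p, J = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rbinom(n_sites, 1, psi)
  H <- matrix(0L, n_sites, J)
  occ <- which(z == 1)
  if (length(occ) > 0)
    H[occ, ] <- matrix(stats::rbinom(length(occ) * J, 1, p), length(occ), J)
  list(histories = H, occupancy = z)
}
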