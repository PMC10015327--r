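#' Logistic occurrence models
#'
#' Maximum-likelihood and Firth bias-reduced logistic regression for binary
#' site-occurrence data, with explicit detection of complete separation.
#' Both fitters share the \code{"occfit"} container used throughout the
#' downstream statistics (scale-of-effect screening, variance partitioning,
#' spatial diagnostics).
#'
#' @name occurrence_glm
NULL

logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

new_occfit <- function(coefficients, vcov, loglik, null_loglik, fitted, y,
                       X, converged, method, separation = FALSE,
                       iterations = NA_integer_, terms = colnames(X)) {
  structure(list(
    coefficients = coefficients,
    vcov = vcov,
    loglik = loglik,
    null_loglik = null_loglik,
    fitted = fitted,
    residuals = y - fitted,      # response residuals (observed - fitted)
    y = y,
    X = X,
    converged = converged,
    separation = separation,
    method = method,
    iterations = iterations,
    terms = terms
  ), class = "occfit")
}

check_design <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("y must be binary 0/1")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) <= ncol(X)) stop("need n > p observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  list(X = X, y = y)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Plain maximum likelihood with a logit link. Convergence is declared when
#' the score (gradient of the log-likelihood) falls below \code{tol} in
#' maximum norm. Complete or quasi-complete separation is detected as
#' coefficient divergence on the standardized scale or failure to converge
#' within \code{max_iter} scoring steps; the fit is then flagged
#' (\code{converged = FALSE}, \code{separation = TRUE}) and the bias-reduced
#' path (\code{\link{fit_firth}}) is the advised remedy.
#'
#' @param X design matrix (include the intercept column explicitly, or use
#'   \code{intercept = TRUE} to prepend one).
#' @param y binary response vector (0/1).
#' @param intercept prepend an intercept column when \code{X} lacks one.
#' @param tol maximum-norm gradient tolerance (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return an object of class \code{"occfit"}: coefficients on the logit
#'   scale, covariance matrix (inverse Fisher information), log-likelihood,
#'   null log-likelihood, fitted probabilities, response residuals and
#'   convergence/separation flags.
#' @examples
#' set.seed(1)
#' x <- rnorm(60)
#' y <- rbinom(60, 1, plogis(-0.5 + x))
#' fit <- fit_logistic(cbind(1, x), y)
#' coef(fit)
#' @export
fit_logistic <- function(X, y, intercept = FALSE, tol = 1e-8, max_iter = 100) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  d <- check_design(X, y)
  X <- d$X; y <- d$y
  if (length(unique(y)) < 2) stop("y contains a single class")
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1     # intercept-like columns judged on the raw scale
  it <- 0L
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    XtWX <- crossprod(X * w, X)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    beta <- beta + step
    if (max(abs(beta * sds)) > 15) { separation <- TRUE; break }
  }
  if (!converged) separation <- TRUE
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X * w, X)
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- logistic_loglik(X, y, beta)
  names(beta) <- colnames(X)
  new_occfit(beta, vc, ll, null_loglik_binary(y), mu, y, X,
             converged = converged, method = "ML",
             separation = separation, iterations = it)
}

null_loglik_binary <- function(y) {
  k <- sum(y); n <- length(y)
  if (k == 0 || k == n) return(0)
  k * log(k / n) + (n - k) * log(1 - k / n)
}

#' Fit a Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell(\beta) + \frac12 \log|I(\beta)|} by modified scoring
#' (score adjusted by hat-value leverages), giving finite estimates even
#' under complete separation. On a saturated 2x2 design this is exactly the
#' classical add-1/2-to-each-cell estimator.
#'
#' @inheritParams fit_logistic
#' @param tol convergence tolerance on the modified score (default 1e-8).
#' @param max_iter maximum scoring iterations.
#' @return an \code{"occfit"} with \code{method = "bias-reduced"}; the
#'   reported \code{loglik} is the unpenalized log-likelihood at the
#'   penalized-likelihood maximizer, and \code{penalized_loglik} carries the
#'   penalized value.
#' @examples
#' # complete separation: ML diverges, Firth stays finite
#' x <- c(rep(0, 5), rep(1, 5)); y <- c(rep(0, 5), rep(1, 5))
#' fit_firth(cbind(1, x), y)$coefficients
#' @export
fit_firth <- function(X, y, intercept = FALSE, tol = 1e-8, max_iter = 200) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  d <- check_design(X, y)
  X <- d$X; y <- d$y
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  penalized <- function(b) {
    eta <- drop(X %*% b); mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(crossprod(X * w, X), logarithm = TRUE)$modulus
  }
  pl_old <- penalized(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * w, X)
    XtWX_inv <- solve(XtWX)
    # leverages of W^(1/2) X
    h <- rowSums((X %*% XtWX_inv) * X) * w
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    step <- drop(XtWX_inv %*% score)
    # trust-region cap: vanishing weights can make the Fisher step explode
    if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
    # step-halving on the penalized likelihood
    fac <- 1
    repeat {
      pl_new <- penalized(beta + fac * step)
      if (pl_new >= pl_old - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) { fac <- 0; break }
    }
    if (fac == 0) { converged <- max(abs(score)) < 1e-4; break }
    beta <- beta + fac * step
    if (max(abs(fac * step)) < 1e-12) { converged <- TRUE; break }
    pl_old <- pl_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  vc <- solve(crossprod(X * w, X))
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  out <- new_occfit(beta, vc, logistic_loglik(X, y, beta),
                    null_loglik_binary(y), mu, y, X,
                    converged = converged, method = "bias-reduced",
                    iterations = it)
  out$penalized_loglik <- as.numeric(pl_old)
  out
}

#' @export
coef.occfit <- function(object, ...) object$coefficients

#' @export
vcov.occfit <- function(object, ...) object$vcov

#' @export
logLik.occfit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.occfit <- function(x, ...) {
  cat(sprintf("Logistic occurrence fit (%s)\n", x$method))
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tab <- data.frame(estimate = x$coefficients, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, 4))
  cat(sprintf("logLik %.4f (null %.4f)  converged: %s%s\n", x$loglik,
              x$null_loglik, x$converged,
              if (isTRUE(x$separation)) "  [separation detected]" else ""))
  invisible(x)
}

#' Model summary table
#'
#' @param fit an \code{"occfit"}.
#' @return data frame with term, estimate, SE, z and p columns.
#' @export
summary_table <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  data.frame(term = fit$terms, estimate = unname(fit$coefficients),
             se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL)
}

#' All pairwise Wald contrasts between factor levels, Bonferroni-adjusted
#'
#' For a fit whose design contains a dummy-coded factor (reference level
#' absorbed in the intercept), computes the Wald contrast between every pair
#' of levels and applies the Bonferroni correction
#' \eqn{p_{adj} = \min(1, m \, p)} with \eqn{m} the number of pairs.
#'
#' @param fit an \code{"occfit"} from a design containing the factor dummies.
#' @param levels character vector of all factor level names, reference first.
#' @param dummy_cols names of the dummy columns in the design, in the same
#'   order as \code{levels[-1]}; defaults to \code{levels[-1]}.
#' @param m number of comparisons used for the correction (defaults to the
#'   number of pairs).
#' @return data frame with one row per level pair: estimate (log-odds
#'   difference), SE, z, raw and adjusted p.
#' @export
pairwise_contrasts <- function(fit, levels, dummy_cols = levels[-1], m = NULL) {
  if (length(levels) < 2) stop("need a factor with >= 2 levels")
  if (!all(dummy_cols %in% fit$terms))
    stop("dummy columns not found in the fit design")
  p <- length(fit$coefficients)
  # coefficient vector per level: reference level = 0
  lev_vec <- function(lv) {
    v <- numeric(p)
    if (lv != levels[1]) {
      j <- match(dummy_cols[match(lv, levels[-1])], fit$terms)
      v[j] <- 1
    }
    v
  }
  pairs <- utils::combn(levels, 2)
  if (is.null(m)) m <- ncol(pairs)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    cvec <- lev_vec(a) - lev_vec(b)
    est <- sum(cvec * fit$coefficients)
    v <- drop(t(cvec) %*% fit$vcov %*% cvec)
    flagged <- v <= 0 || !is.finite(v)
    se <- if (flagged) NA_real_ else sqrt(v)
    z <- if (flagged) NA_real_ else est / se
    praw <- if (flagged) NA_real_ else 2 * stats::pnorm(-abs(z))
    data.frame(level_a = a, level_b = b, estimate = est, se = se, z = z,
               p = praw, p_adjusted = pmin(1, m * praw), flagged = flagged)
  })
  do.call(rbind, out)
}

#' Predicted occurrence probabilities with confidence bands
#'
#' Inverse-logit of the linear predictor with delta-method intervals built on
#' the logit scale and transformed, so the endpoints always lie in (0, 1).
#'
#' @param fit an \code{"occfit"}.
#' @param newX design matrix for prediction; columns must match the fit.
#' @param level confidence level (default 0.95).
#' @return data frame with fit, lower and upper probability columns.
#' @export
predict_response <- function(fit, newX, level = 0.95) {
  newX <- as.matrix(newX)
  if (ncol(newX) != length(fit$coefficients))
    stop("newX columns do not match the fitted design")
  if (!is.null(colnames(newX)) && !identical(colnames(newX), fit$terms))
    stop("newX column names do not match the fitted design")
  eta <- drop(newX %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((newX %*% fit$vcov) * newX), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = stats::plogis(eta),
             lower = stats::plogis(eta - zq * se),
             upper = stats::plogis(eta + zq * se))
}

#' Empirical tipping-point boundary
#'
#' The species-occurrence boundary as the paper-style empirical statement:
#' for \code{direction = "presence-above"} the minimum covariate value among
#' presences (all presences lie above it); for \code{"presence-below"} the
#' maximum among presences. Absences on the presence side of the boundary
#' are counted, not hidden.
#'
#' @param y binary occurrence.
#' @param covariate numeric covariate (same length).
#' @param direction \code{"presence-above"} or \code{"presence-below"}.
#' @return list with boundary value, direction and the number of absences
#'   beyond the boundary (on the presence side).
#' @export
tipping_point <- function(y, covariate,
                          direction = c("presence-above", "presence-below")) {
  direction <- match.arg(direction)
  y <- as.numeric(y)
  if (length(y) != length(covariate)) stop("length mismatch")
  if (all(y == 1) || all(y == 0)) stop("both classes must be present")
  if (length(unique(covariate)) < 2) stop("degenerate covariate")
  pres <- covariate[y == 1]; abs_ <- covariate[y == 0]
  if (direction == "presence-above") {
    boundary <- min(pres)
    n_beyond <- sum(abs_ >= boundary)
  } else {
    boundary <- max(pres)
    n_beyond <- sum(abs_ <= boundary)
  }
  list(covariate = deparse(substitute(covariate)), direction = direction,
       boundary = boundary, n_absences_beyond = n_beyond)
}
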