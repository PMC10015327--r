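#' Spatial diagnostics and the autocovariate predictor
#'
#' Moran's I on model residuals with an inverse-distance weight matrix, an
#' empirical variogram, and the distance-weighted autocovariate used to
#' absorb residual spatial autocorrelation in occurrence models.
#'
#' @name spatial_stats
NULL

pair_dist <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must be an n x 2 matrix")
  as.matrix(stats::dist(coords))
}

#' Inverse-distance spatial weights
#'
#' Global inverse-distance weights \eqn{w_{ij} = 1/d_{ij}} (optionally
#' \eqn{1/d_{ij}^2}) with zero diagonal, optionally thresholded at a
#' neighbourhood radius and optionally row-standardized.
#'
#' @param coords n x 2 matrix of projected coordinates (m).
#' @param scheme \code{"inverse"} or \code{"inverse_squared"}.
#' @param radius neighbourhood cutoff in metres (\code{Inf} = global).
#' @param row_standardize divide each row by its sum.
#' @return list of class \code{"spatial_weights"} with the weight matrix and
#'   the scheme metadata.
#' @export
spatial_weights <- function(coords, scheme = c("inverse", "inverse_squared"),
                            radius = Inf, row_standardize = FALSE) {
  scheme <- match.arg(scheme)
  d <- pair_dist(coords)
  n <- nrow(d)
  if (n < 2) stop("need at least two sites")
  off <- d[upper.tri(d)]
  if (any(off == 0)) stop("coincident sites (zero distance) not allowed")
  w <- if (scheme == "inverse") 1 / d else 1 / d^2
  diag(w) <- 0
  w[d > radius] <- 0
  if (any(rowSums(w) == 0)) stop("every site needs at least one neighbour")
  if (row_standardize) w <- w / rowSums(w)
  structure(list(w = w, scheme = scheme, radius = radius,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Moran's I with normal-approximation inference
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the centred values and \eqn{S_0 = \sum_{ij} w_{ij}}.
#' Expectation is exactly \eqn{-1/(n-1)}; the variance uses the standard
#' normality-assumption formula and p is the two-sided normal tail.
#'
#' @param values numeric vector (typically model response residuals).
#' @param weights a \code{"spatial_weights"} object, or an n x n weight
#'   matrix with zero diagonal.
#' @return list of class \code{"moran_result"}: \code{I}, \code{expected},
#'   \code{variance}, \code{p}.
#' @export
morans_i <- function(values, weights) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else as.matrix(weights)
  n <- length(values)
  if (n < 3) stop("need n >= 3")
  if (!all(dim(w) == n)) stop("weight matrix does not match values")
  z <- values - mean(values)
  if (sum(z^2) == 0) stop("zero-variance values")
  s0 <- sum(w)
  cp <- drop(t(z) %*% w %*% z)
  I <- (n / s0) * cp / sum(z^2)
  # normality-assumption variance
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  eI <- -1 / (n - 1)
  vI <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - eI^2
  p <- 2 * stats::pnorm(-abs((I - eI) / sqrt(vI)))
  structure(list(I = I, expected = eI, variance = vI, p = p, n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, sd %.4f), p = %.4g\n",
              x$I, x$expected, sqrt(x$variance), x$p))
  invisible(x)
}

#' Distance-weighted autocovariate
#'
#' For each site, the inverse-distance weighted average of neighbouring
#' response values, \eqn{A_i = \sum_j w_{ij} y_j / \sum_j w_{ij}} with
#' \eqn{w_{ij} = 1/d_{ij}}. Neighbours are sites within a per-site radius
#' \code{max(min_neighbour_dist, nearest-neighbour distance)}, so no site is
#' left neighbourless; the default minimum neighbour distance is 210 m.
#'
#' @param y binary (or numeric) response vector.
#' @param coords n x 2 coordinate matrix (m).
#' @param min_neighbour_dist minimum neighbourhood radius in metres.
#' @return numeric vector of autocovariate values, invariant to rescaling of
#'   the distance units.
#' @export
autocovariate <- function(y, coords, min_neighbour_dist = 210) {
  d <- pair_dist(coords)
  n <- length(y)
  if (nrow(d) != n) stop("coords do not match y")
  off <- d[upper.tri(d)]
  if (any(off == 0)) stop("coincident sites (zero distance) not allowed")
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    radius <- max(min_neighbour_dist, min(di))
    nb <- which(di <= radius)
    w <- 1 / di[nb]
    sum(w * y[-i][nb]) / sum(w)
  }, numeric(1))
}

#' Empirical semivariogram
#'
#' Bins all site pairs by separation distance and reports
#' \eqn{\gamma(h) = \mathrm{mean}\ \frac12 (z_i - z_j)^2} per bin. Empty
#' bins are reported with pair count 0 and NA semivariance.
#'
#' @param values numeric vector.
#' @param coords n x 2 coordinate matrix.
#' @param n_bins number of equal-width distance bins.
#' @param max_dist upper distance bound (defaults to the maximum pair
#'   distance).
#' @return data frame with lag midpoint, semivariance and pair count per bin.
#' @export
empirical_variogram <- function(values, coords, n_bins = 10,
                                max_dist = NULL) {
  n <- length(values)
  if (n < 2) stop("need at least two sites")
  d <- pair_dist(coords)
  iu <- upper.tri(d)
  dd <- d[iu]
  gg <- 0.5 * outer(values, values, "-")[iu]^2
  if (is.null(max_dist)) max_dist <- max(dd)
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dd, breaks, include.lowest = TRUE, labels = FALSE)
  mid <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  counts <- tabulate(bin, nbins = n_bins)
  gamma <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) if (counts[b] > 0) gamma[b] <- mean(gg[bin == b])
  data.frame(lag = mid, semivariance = gamma, n_pairs = counts)
}
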