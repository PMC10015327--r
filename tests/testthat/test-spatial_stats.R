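test_that("Moran's I equals the brute-force double loop to 1e-12", {
  # 4 sites on a unit square, values paired by side, rook weights
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  vals <- c(1, 1, -1, -1)
  w <- matrix(0, 4, 4)
  rook <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4))
  w[rook] <- 1; w[rook[, 2:1]] <- 1
  m <- morans_i(vals, w)
  expect_equal(m$I, moran_brute(vals, w), tolerance = 1e-12)
  expect_equal(m$expected, -1 / 3)
  # and on random inverse-distance weights
  set.seed(1)
  coords2 <- matrix(stats::runif(30) * 1000, 15, 2)
  sw <- spatial_weights(coords2)
  v2 <- stats::rnorm(15)
  expect_equal(morans_i(v2, sw)$I, moran_brute(v2, sw$w), tolerance = 1e-12)
  expect_error(morans_i(rep(1, 15), sw), "zero-variance")
})

test_that("Moran's I agrees with the ape oracle under row standardization", {
  skip_if_not_installed("ape")
  set.seed(2)
  coords <- matrix(stats::runif(60) * 2000, 30, 2)
  vals <- stats::rnorm(30)
  ours <- morans_i(vals, spatial_weights(coords, row_standardize = TRUE))
  ref <- ape::Moran.I(vals, spatial_weights(coords)$w)  # ape row-normalizes
  expect_equal(ours$I, ref$observed, tolerance = 1e-10)
  expect_equal(ours$expected, ref$expected, tolerance = 1e-10)
})

test_that("permutation mean of I is the expectation and clustering is positive", {
  set.seed(3)
  coords <- matrix(stats::runif(40) * 1000, 20, 2)
  sw <- spatial_weights(coords)
  vals <- stats::rnorm(20)
  perms <- replicate(500, morans_i(sample(vals), sw)$I)
  expect_lt(abs(mean(perms) - (-1 / 19)), 3 * stats::sd(perms) / sqrt(500))
  # two distant clusters with constant-by-cluster values -> I > 0
  cl <- rbind(matrix(stats::runif(20, 0, 100), 10, 2),
              matrix(stats::runif(20, 5000, 5100), 10, 2))
  vcl <- c(rep(1, 10), rep(-1, 10)) + stats::rnorm(20, 0, 0.01)
  expect_gt(morans_i(vcl, spatial_weights(cl))$I, 0)
})

test_that("autocovariate is the hand-computed weighted mean of neighbours", {
  # neighbours at 100 m (y=1) and 200 m (y=0): A = (1/100)/(1/100+1/200) = 2/3
  coords <- rbind(c(0, 0), c(100, 0), c(0, 200))
  a <- autocovariate(c(0, 1, 0), coords, min_neighbour_dist = 210)
  expect_equal(a[1], 2 / 3, tolerance = 1e-12)
  # constants pass through; zeros stay zero
  expect_equal(autocovariate(c(1, 1, 1), coords), rep(1, 3))
  expect_equal(autocovariate(c(0, 0, 0), coords), rep(0, 3))
  # unit-rescaling invariance
  set.seed(4)
  c2 <- matrix(stats::runif(40) * 3000, 20, 2)
  y2 <- stats::rbinom(20, 1, 0.5)
  expect_equal(autocovariate(y2, c2, 210), autocovariate(y2, c2 / 1000, 0.210),
               tolerance = 1e-12)
  # isolated site adopts its nearest neighbour (adaptive radius)
  c3 <- rbind(c(0, 0), c(5000, 0), c(5100, 0))
  a3 <- autocovariate(c(0, 1, 1), c3, 210)
  expect_equal(a3[1], 1)   # only neighbour within max(210, 5000) at 5000 m
  expect_error(autocovariate(c(0, 1), rbind(c(0, 0), c(0, 0))), "coincident")
})

test_that("variogram shapes: flat for noise, increasing for a gradient", {
  set.seed(5)
  coords <- matrix(stats::runif(400) * 1000, 200, 2)
  # white noise: no bin should deviate wildly from the overall variance
  vn <- stats::rnorm(200)
  vg <- empirical_variogram(vn, coords, n_bins = 6)
  dense <- which(vg$n_pairs >= 100)
  # well-filled bins stay flat: within 25% of the process variance
  # (pairs are not independent, so the envelope is generous)
  expect_true(all(vg$semivariance[dense] / stats::var(vn) > 0.75 &
                    vg$semivariance[dense] / stats::var(vn) < 1.25))
  # smooth gradient: semivariance increases with lag
  vgrad <- coords[, 1] / 1000
  vg2 <- empirical_variogram(vgrad, coords, n_bins = 5)
  expect_true(all(diff(vg2$semivariance[!is.na(vg2$semivariance)]) > -0.01))
  # two sites -> single bin with gamma = (z1 - z2)^2 / 2
  vg3 <- empirical_variogram(c(3, 1), rbind(c(0, 0), c(10, 0)), n_bins = 1)
  expect_equal(vg3$semivariance, 2)
  expect_equal(vg3$n_pairs, 1L)
})

test_that("autocovariate absorbs the spatial field's residual autocorrelation", {
  # non-spatial fit on spatial-field data shows Moran p < 0.05; adding the
  # autocovariate (neighbourhood matched to the field range) removes it
  st <- synth_sites(220, region = c(12000, 12000), min_dist = 400, seed = 9)
  set.seed(43)
  cov <- data.frame(forest_cover_200 = stats::runif(220, 0, 100))
  tr <- occurrence_truth(forest_slope = 0.08, spatial_sd = 2,
                         spatial_range = 2500, road_exclusion_col = NULL)
  o <- synth_occurrence(st, cov, tr, seed = 3)
  X0 <- cbind(1, stats::poly(cov$forest_cover_200, 2))
  colnames(X0) <- c("(Intercept)", "c1", "c2")
  f0 <- fit_logistic(X0, o$occurrence)
  w <- spatial_weights(cbind(st$x, st$y))
  expect_lt(morans_i(f0$residuals, w)$p, 0.05)
  ac <- autocovariate(o$occurrence, cbind(st$x, st$y),
                      min_neighbour_dist = 1500)
  f1 <- fit_logistic(cbind(X0, ac = ac), o$occurrence)
  expect_gt(morans_i(f1$residuals, w)$p, 0.05)
  # with the field disabled, residual I sits near its expectation
  o2 <- synth_occurrence(st, cov,
                         occurrence_truth(forest_slope = 0.08,
                                          road_exclusion_col = NULL), seed = 3)
  f2 <- fit_logistic(X0, o2$occurrence)
  expect_gt(morans_i(f2$residuals, w)$p, 0.05)
})
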