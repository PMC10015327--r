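test_that("fit_logistic matches closed forms on saturated designs", {
  # intercept only: logit(k/n)
  y <- c(rep(1, 7), rep(0, 3))
  f <- fit_logistic(matrix(1, 10, 1), y)
  expect_equal(unname(f$coefficients), log(7 / 3), tolerance = 1e-8)
  # 2x2 table (10,5; 5,10): slope log((10*10)/(5*5)) = log 4
  y2 <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  x2 <- c(rep(1, 15), rep(0, 15))
  f2 <- fit_logistic(cbind(1, x2), y2)
  expect_equal(unname(f2$coefficients[2]), log(4), tolerance = 1e-8)
  expect_true(f2$converged)
  # agreement with glm as an independent oracle on a random design
  set.seed(2)
  X <- cbind(1, stats::rnorm(80), stats::rnorm(80))
  yy <- stats::rbinom(80, 1, stats::plogis(X %*% c(-0.2, 1, -0.5)))
  ours <- fit_logistic(X, yy)
  ref <- stats::glm.fit(X, yy, family = stats::binomial())
  expect_equal(unname(ours$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
})

test_that("complete separation is detected and flagged", {
  y <- c(rep(0, 8), rep(1, 8))
  x <- c(rep(0, 8), rep(1, 8))
  f <- fit_logistic(cbind(1, x), y)
  expect_false(f$converged)
  expect_true(f$separation)
  expect_error(fit_logistic(cbind(1, x), rep(1, 16)), "single class")
})

test_that("Firth fit equals the add-half closed form on 2x2 designs", {
  # (5,0; 3,4): slope log((5.5*4.5)/(0.5*3.5))
  y <- c(rep(1, 5), rep(1, 3), rep(0, 4))
  x <- c(rep(1, 5), rep(0, 7))
  f <- fit_firth(cbind(1, x), y)
  expect_equal(unname(f$coefficients[2]), log((5.5 * 4.5) / (0.5 * 3.5)),
               tolerance = 1e-6)
  # all-success intercept-only n=10: logit(10.5/0.5) finite where ML diverges
  fa <- fit_firth(matrix(1, 10, 1), rep(1, 10))
  expect_equal(unname(fa$coefficients), log(10.5 / 0.5), tolerance = 1e-6)
  # near ML on well-separated data
  set.seed(4)
  X <- cbind(1, stats::rnorm(400))
  yy <- stats::rbinom(400, 1, stats::plogis(X %*% c(0.2, 0.7)))
  fm <- fit_logistic(X, yy)
  ff <- fit_firth(X, yy)
  expect_lt(max(abs(fm$coefficients - ff$coefficients)), 0.05)
})

test_that("deviance is monotone under nesting", {
  set.seed(5)
  X <- cbind(1, stats::rnorm(100), stats::rnorm(100))
  y <- stats::rbinom(100, 1, stats::plogis(X[, 2]))
  l1 <- fit_logistic(X[, 1:2], y)$loglik
  l2 <- fit_logistic(X, y)$loglik
  expect_gte(l2, l1 - 1e-10)
})

test_that("pairwise contrasts apply the Bonferroni cap", {
  set.seed(6)
  lu <- factor(sample(c("og", "sec", "grass"), 120, replace = TRUE),
               levels = c("og", "sec", "grass"))
  X <- stats::model.matrix(~lu)
  colnames(X) <- c("(Intercept)", "lusec", "lugrass")
  y <- stats::rbinom(120, 1, stats::plogis(-0.3 + 2 * (lu == "grass")))
  f <- fit_logistic(X, y)
  cc <- pairwise_contrasts(f, levels = c("og", "sec", "grass"),
                           dummy_cols = c("lusec", "lugrass"))
  expect_equal(nrow(cc), 3)
  expect_equal(cc$p_adjusted, pmin(1, 3 * cc$p))
  expect_true(all(cc$p_adjusted <= 1))
  # m-scaling and the cap itself
  cc10 <- pairwise_contrasts(f, levels = c("og", "sec", "grass"),
                             dummy_cols = c("lusec", "lugrass"), m = 10)
  expect_equal(cc10$p_adjusted, pmin(1, 10 * cc10$p))
})

test_that("predicted probabilities and CIs are well-formed and calibrated", {
  set.seed(7)
  n <- 200
  x <- stats::rnorm(n)
  X <- cbind(1, x)
  y <- stats::rbinom(n, 1, stats::plogis(-0.3 + 0.8 * x))
  f <- fit_logistic(X, y)
  newX <- cbind(1, c(-1, 0, 1))
  pr <- predict_response(f, newX)
  expect_true(all(pr$lower > 0 & pr$upper < 1))
  expect_true(all(pr$lower < pr$fit & pr$fit < pr$upper))
  # centred fit: prediction at the covariate mean is plogis(intercept)
  xc <- x - mean(x)
  fc <- fit_logistic(cbind(1, xc), y)
  prc <- predict_response(fc, cbind(1, 0))
  expect_equal(prc$fit, stats::plogis(unname(fc$coefficients[1])),
               tolerance = 1e-10)
  expect_error(predict_response(f, cbind(1, 0, 0)), "match")
  # delta-method SE vs 1000-draw parametric bootstrap within 10%
  se_delta <- {
    eta <- drop(newX %*% f$coefficients)
    se_eta <- sqrt(rowSums((newX %*% f$vcov) * newX))
    stats::plogis(eta) * (1 - stats::plogis(eta)) * se_eta
  }
  set.seed(8)
  boot <- replicate(1000, {
    ys <- stats::rbinom(n, 1, f$fitted)
    fb <- fit_logistic(X, ys)
    stats::plogis(drop(newX %*% fb$coefficients))
  })
  expect_lt(max(abs(apply(boot, 1, stats::sd) - se_delta) / se_delta), 0.10)
})

test_that("tipping points are the empirical data boundaries", {
  y <- c(1, 1, 1, 0, 0, 0)
  cov <- c(85, 92, 99, 10, 40, 83)
  tp <- tipping_point(y, cov, "presence-above")
  expect_equal(tp$boundary, 85)
  expect_equal(tp$n_absences_beyond, 0)   # no absence at/above 85? 83 < 85
  tp2 <- tipping_point(c(1, 1, 0, 0), c(0.2, 0.5, 0.7, 0.9), "presence-below")
  expect_equal(tp2$boundary, 0.5)
  expect_error(tipping_point(rep(1, 4), 1:4), "classes")
  expect_error(tipping_point(c(1, 0), c(2, 2)), "degenerate")
})

test_that("both fitters recover generating coefficients within 2 SE", {
  # parameter recovery at n = 341 across seeded replicates
  beta <- c(-0.5, 0.8)
  cover_ml <- 0; cover_fi <- 0
  R <- 60
  set.seed(9)
  for (r in seq_len(R)) {
    X <- cbind(1, stats::rnorm(341))
    y <- stats::rbinom(341, 1, stats::plogis(drop(X %*% beta)))
    fm <- fit_logistic(X, y)
    ff <- fit_firth(X, y)
    if (all(abs(fm$coefficients - beta) <= 2 * sqrt(diag(fm$vcov))))
      cover_ml <- cover_ml + 1
    if (all(abs(ff$coefficients - beta) <= 2 * sqrt(diag(ff$vcov))))
      cover_fi <- cover_fi + 1
  }
  expect_gte(cover_ml / R, 0.93)
  expect_gte(cover_fi / R, 0.93)
})
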