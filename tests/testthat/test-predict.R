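small_cb <- function() {
  set.seed(20)
  Q <- matrix(runif(12, 0, 10), 4, 3)
  build_crossbasis(Q,
                   basis_spec("bspline", 2, numeric(0), c(0, 10)),  # v_x = 2
                   basis_spec("bspline", 2, numeric(0), c(0, 2),
                              intercept = FALSE),                   # v_l = 2
                   lag_grid = 0:2, check_rank = FALSE)
}

test_that("predictions vanish at the reference exposure", {
  cb <- small_cb()
  fit <- toy_fit(cb, eta = c(0.3, -0.2, 0.1, 0.4))
  lc <- predict_lag_curve(fit, x_p = 0, lag_grid = 0:2, x0 = 0)
  expect_equal(lc$loghr, rep(0, 3))
  expect_equal(lc$hr, rep(1, 3))
  ec <- predict_exposure_curve(fit, lag_p = 1, x_grid = c(0, 3), x0 = 3)
  expect_equal(ec$loghr[2], 0)
})

test_that("a constant-lag DLM predicts a flat unit-exposure lag curve", {
  p <- exposure_profile("a", 1:50, runif(50, 0, 10))
  Q <- build_history_matrix(list(p), data.frame(subject_id = "a", time = 50),
                            2, 40)
  cb <- build_crossbasis(Q, basis_spec("linear", boundary = c(0, 10)),
                         basis_spec("constant"))
  fit <- toy_fit(cb, eta = 0.05, vcov = matrix(4e-4))
  lc <- predict_lag_curve(fit, x_p = 1, x0 = 0)
  expect_equal(lc$loghr, rep(0.05, 39))
  expect_equal(lc$se, rep(0.02, 39))
})

test_that("curves, surfaces and cumulative effects match the brute-force oracle", {
  cb <- small_cb()
  set.seed(21)
  eta <- rnorm(4, 0, 0.3)
  fit <- toy_fit(cb, eta)
  x0 <- 1
  # lag curve at x_p = 4
  lc <- predict_lag_curve(fit, 4, 0:2, x0 = x0)
  for (i in 1:3)
    expect_equal(lc$loghr[i],
                 brute_pred_point(4, i - 1, cb$fx_spec, cb$wl_spec, eta, x0),
                 tolerance = 1e-10)
  # exposure curve at lag 2
  xg <- c(1, 3.5, 8)
  ec <- predict_exposure_curve(fit, 2, xg, x0 = x0)
  for (i in seq_along(xg))
    expect_equal(ec$loghr[i],
                 brute_pred_point(xg[i], 2, cb$fx_spec, cb$wl_spec, eta, x0),
                 tolerance = 1e-10)
  # surface slices agree with the curves
  g <- predict_grid(fit, xg, 0:2, x0 = x0)
  expect_equal(unname(g$betahat[, 3]), ec$loghr, tolerance = 1e-12)
  expect_equal(unname(g$betahat[2, ]),
               predict_lag_curve(fit, 3.5, 0:2, x0 = x0)$loghr,
               tolerance = 1e-12)
  expect_equal(unname(g$se[, 3]), ec$se, tolerance = 1e-12)
  # cumulative effect of a varying history
  q_h <- c(2, 7, 0.5)
  ce <- cumulative_effect(fit, q_h, x0 = x0)
  expect_equal(ce$loghr,
               brute_cumulative(q_h, 0:2, cb$fx_spec, cb$wl_spec, eta, x0),
               tolerance = 1e-10)
  # decomposition: cumulative = sum of per-lag contributions
  parts <- vapply(1:3, function(i)
    brute_pred_point(q_h[i], i - 1, cb$fx_spec, cb$wl_spec, eta, x0),
    numeric(1))
  expect_equal(ce$loghr, sum(parts), tolerance = 1e-10)
  # all-zero coefficients give an all-zero surface
  fit0 <- toy_fit(cb, rep(0, 4))
  expect_true(all(predict_grid(fit0, xg, 0:2, x0 = 0)$betahat == 0))
})

test_that("the cumulative hazard ratio has the closed form for a constant-lag DLM", {
  # per-lag HR of 1.031 per 100 WLM, constant over lags 2-40; exposure of
  # 20 WLM/year in the last 10 years has 8 in-window years: HR = 1.031^1.6
  p <- exposure_profile("a", 1:50, c(rep(0, 40), rep(20, 10)))
  Q <- build_history_matrix(list(p), data.frame(subject_id = "a", time = 50),
                            2, 40)
  cb <- build_crossbasis(Q, basis_spec("linear", boundary = c(0, 200)),
                         basis_spec("constant"))
  fit <- toy_fit(cb, eta = log(1.031) / 100, vcov = matrix(1e-8))
  q_h <- ifelse(2:40 <= 9, 20, 0)
  ce <- cumulative_effect(fit, q_h, x0 = 0)
  expect_equal(ce$hr, 1.031^1.6, tolerance = 1e-12)
  expect_equal(ce$hr, 1.05, tolerance = 5e-4)
  # additivity of the cumulative log-HR for linear f(x)
  q1 <- ifelse(2:40 <= 9, 20, 0); q2 <- ifelse(2:40 >= 30, 5, 0)
  ces <- vapply(list(q1, q2, q1 + q2), function(q)
    cumulative_effect(fit, q, x0 = 0)$loghr, numeric(1))
  expect_equal(ces[1] + ces[2], ces[3], tolerance = 1e-12)
})

test_that("delta-method standard errors match a parametric bootstrap", {
  cb <- small_cb()
  set.seed(22)
  eta <- rnorm(4, 0, 0.3)
  fit <- toy_fit(cb, eta)
  q_h <- c(2, 7, 0.5)
  ce <- cumulative_effect(fit, q_h, x0 = 0)
  # the predictor is linear in eta; get its gradient from the brute-force
  # oracle at unit coefficient vectors, then propagate N(eta, V) draws
  g <- vapply(1:4, function(j)
    brute_cumulative(q_h, 0:2, cb$fx_spec, cb$wl_spec,
                     replace(rep(0, 4), j, 1), 0), numeric(1))
  L <- t(chol(fit$vcov))
  draws <- vapply(1:20000, function(i)
    sum(g * (eta + drop(L %*% rnorm(4)))), numeric(1))
  expect_equal(sd(draws), ce$se, tolerance = 0.03)
})

test_that("risk trajectories track the history through the lag window", {
  lagw <- c(0, 6)
  p0 <- exposure_profile("z", 1:40, rep(0, 40))
  Q <- build_history_matrix(list(p0), data.frame(subject_id = "z", time = 20),
                            lagw[1], lagw[2])
  wl <- basis_spec("bspline", 2, 3, c(0, 6), intercept = FALSE,
                   right_constrained = TRUE)
  cb <- build_crossbasis(Q, basis_spec("linear", boundary = c(0, 50)), wl,
                         check_rank = FALSE)
  fit <- toy_fit(cb, eta = rep(0.2, ncol(cb$W)),
                 vcov = diag(ncol(cb$W)) * 1e-6)
  tr0 <- risk_trajectory(fit, p0, 10:20)
  expect_equal(tr0$loghr, rep(0, 11))
  # a pulse at year 10 leaves the lag window after L years under a
  # left+right-constrained lag basis
  pp <- exposure_profile("p", 1:40, replace(rep(0, 40), 10, 30))
  tr <- risk_trajectory(fit, pp, c(9, 12, 16, 17, 20))
  expect_equal(tr$loghr[1], 0)                 # before the pulse
  expect_gt(max(abs(tr$loghr[2:3])), 0)        # inside the window
  expect_equal(tr$loghr[4:5], c(0, 0), tolerance = 1e-12)  # beyond lag L
})

test_that("out-of-range prediction points are refused", {
  cb <- small_cb()
  fit <- toy_fit(cb, rep(0.1, 4))
  expect_error(predict_lag_curve(fit, 15, 0:2, x0 = 0), "boundary")
  expect_error(cumulative_effect(fit, c(1, 2), x0 = 0), "per lag")
})
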