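test_that("SIMPLS reproduces exact linear relations", {
  set.seed(1)
  # with as many components as (informative) predictors, PLS1 equals OLS
  X <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(NULL, paste0("x", 1:2)))
  y <- 2 * X[, 1] - 3 * X[, 2] + 5
  f <- simpls_fit(X, y, n_components = 2)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(f$fitted, y, tolerance = 1e-8)
  expect_equal(predict(f, X[3, ]), y[3], tolerance = 1e-8)
})

test_that("SIMPLS coefficients match a NIPALS PLS1 oracle on random tables", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:9, 1); p <- sample(3:7, 1)
    A <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    f <- simpls_fit(X, y, A)
    o <- nipals_pls1(X, y, A)
    expect_equal(unname(f$coef_raw), unname(o$coef_raw), tolerance = 1e-8)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-8)
  }
})

test_that("with n_components = rows - 1 and full rank, PLS equals OLS", {
  set.seed(3)
  X <- matrix(rnorm(6 * 3), 6, 3)
  y <- rnorm(6)
  f <- simpls_fit(X, y, n_components = 3)
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(f$fitted, unname(ols$fitted.values), tolerance = 1e-8)
})

test_that("VIP scores satisfy their identities and formula", {
  # single informative column in an orthogonal (Hadamard) design:
  # its VIP is exactly sqrt(p), the inert columns score 0
  X <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1), d = c(1, -1, -1, 1))
  f1 <- simpls_fit(X, 3 * X[, "a"], 1)
  v1 <- vip_scores(f1)
  expect_equal(unname(v1), c(sqrt(3), 0, 0), tolerance = 1e-10)

  # mean of squared VIPs is 1 for every fit
  for (i in 1:10) {
    Xr <- matrix(rnorm(7 * 5), 7, 5)
    yr <- rnorm(7)
    fr <- simpls_fit(Xr, yr, 2)
    expect_equal(mean(vip_scores(fr)^2), 1, tolerance = 1e-10)
    # direct-formula oracle
    wn <- sweep(fr$R, 2, sqrt(colSums(fr$R^2)), "/")
    vor <- sqrt(5 * as.numeric(wn^2 %*% fr$ssy) / sum(fr$ssy))
    expect_equal(unname(vip_scores(fr)), vor, tolerance = 1e-10)
  }
})

test_that("zero-variance columns are dropped with a warning", {
  X <- cbind(a = rnorm(6), b = rep(2, 6), d = rnorm(6))
  expect_warning(f <- simpls_fit(X, rnorm(6), 2), "zero-variance")
  expect_identical(unname(f$coef_raw["b"]), 0)
  expect_true(is.na(vip_scores(f)["b"]))
})

test_that("Q2Y matches a hand-rolled leave-one-out computation", {
  set.seed(11)
  X <- matrix(rnorm(5 * 4), 5, 4)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(5, sd = 0.05)
  q <- q2y_loo(X, y, n_components = 2)
  press <- tss <- 0
  for (i in 1:5) {
    f <- simpls_fit(X[-i, ], y[-i], 2)
    press <- press + (y[i] - predict(f, X[i, , drop = FALSE]))^2
    tss <- tss + (y[i] - mean(y[-i]))^2
  }
  expect_identical(q, 1 - press / tss)

  # ample rows + perfect relation -> Q2Y ~ 1
  X2 <- matrix(rnorm(30 * 3), 30, 3)
  y2 <- 2 * X2[, 2] + 1
  expect_equal(q2y_loo(X2, y2, 3), 1, tolerance = 1e-6)

  # pure-noise responses predict worse than the mean (on average)
  set.seed(12)
  qs <- replicate(100, {
    Xn <- matrix(rnorm(8 * 5), 8, 5)
    q2y_loo(Xn, rnorm(8), 2)
  })
  expect_lt(mean(qs), 0)
  expect_error(q2y_loo(X[1:3, ], y[1:3], 2), "n_components \\+ 2 rows")
})

test_that("ensemble insulin predictions average the member models", {
  set.seed(21)
  X <- matrix(rnorm(6 * 5), 6, 5, dimnames = list(NULL, paste0("r", 1:5)))
  y <- X %*% c(1, -1, 0.5, 0, 0) + 2
  f1 <- simpls_fit(X, y, 2)
  f2 <- simpls_fit(X + rnorm(30, sd = 0.1), y, 2)
  v <- X[2, ]
  expect_equal(predict_insulin(list(f1, f1), v), predict_insulin(f1, v))
  expect_equal(predict_insulin(list(f1, f2), v),
               mean(c(predict(f1, v), predict(f2, v))))
})

test_that("autoscaling makes predictions and VIP invariant to column units", {
  set.seed(31)
  X <- matrix(runif(7 * 4, 1, 2), 7, 4)
  y <- rnorm(7)
  f1 <- simpls_fit(X, y, 2)
  X2 <- X; X2[, 3] <- X2[, 3] * 1000
  f2 <- simpls_fit(X2, y, 2)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-10)
  expect_equal(unname(vip_scores(f1)), unname(vip_scores(f2)),
               tolerance = 1e-10)
  new1 <- X[4, ]; new2 <- X2[4, ]
  expect_equal(predict(f1, new1), predict(f2, new2), tolerance = 1e-10)
})

test_that("time-resolved PLSR builds per-minute courses", {
  fx <- make_fixture_network()
  prot <- stimulation_protocol(data.frame(duration = c(120, 16),
                                          GLC_e = c(2.8, 16.7)))
  tr <- simulate(fx, protocol = prot, rtol = 1e-6, atol = 1e-9)
  pm <- per_minute_fluxes(tr, 136)[121:136, ]
  rownames(pm) <- 1:16
  res3 <- suppressWarnings(timecourse_plsr(pm, fc_total = 2.4, duration = 3))
  expect_identical(nrow(res3$fit$scores), 3L)
  expect_equal(res3$response[3], 2.4)          # endpoint reconstruction
  expect_lt(res3$fit$n_components, 3)          # reduced with warning
  expect_warning(timecourse_plsr(pm, 2.4, duration = 3), "at most")

  res15 <- timecourse_plsr(pm, fc_total = 3, duration = 15)
  expect_identical(res15$fit$n_components, 3L)
  expect_equal(res15$response, 1 + 2 * (1:15) / 15)

  # constant fluxes + linear response: one component fits exactly
  Xc <- cbind(a = 1:10, b = 2 * (1:10))
  resc <- suppressWarnings(timecourse_plsr(Xc, fc_total = 2, duration = 10,
                                           n_components = 1))
  expect_equal(resc$fit$r2, 1, tolerance = 1e-10)
})
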