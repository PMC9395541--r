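test_that("adjusted R^2 matches the closed-form definition", {
  obs <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(adjusted_r2(obs, obs, 3), 1)
  # predicting the mean: R^2 = 0, n = 10, p = 2 -> 1 - 9/7
  expect_equal(adjusted_r2(obs, rep(mean(obs), 10), 2), 1 - 9 / 7)
  # R^2 = 0.9, n = 11, p = 3 -> 1 - 0.1 * 10 / 7
  set.seed(4)
  y <- rnorm(11)
  tss <- sum((y - mean(y))^2)
  resid <- y - mean(y)
  pred <- y - resid * sqrt(0.1 * tss / sum(resid^2))
  expect_equal(adjusted_r2(y, pred, 3), 1 - 0.1 * 10 / 7, tolerance = 1e-10)
  # monotone decreasing in the parameter count at fixed R^2 and n
  vals <- vapply(1:6, function(p) adjusted_r2(y, pred, p), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(adjusted_r2(1:3, 1:3, 2), "n > n_params")
})

test_that("half-life and residence time invert the decay rate", {
  expect_equal(half_life(1), log(2))
  expect_equal(half_life(0.5), log(2) / 0.5)
  expect_equal(half_life(log(2)), 1)
  expect_equal(mean_residence(0.5), 2)
  expect_equal(mean_residence(1), 1)
  expect_equal(mean_residence(2), 0.5)
  for (k in c(0.3, 0.77, 2.5)) {
    expect_equal(half_life(k) * k, log(2))
    expect_equal(mean_residence(k) * k, 1)
  }
  expect_error(half_life(0), "positive")
  expect_error(mean_residence(-1), "positive")
})

test_that("exponential decay fit recovers noiseless parameters exactly", {
  t <- seq(0, 5, by = 0.5)
  for (k in c(0.5, 0.75)) {
    y <- 7 + 8 * exp(-k * t)
    f <- fit_wbc_decay(t, y, t_peak = 0)
    expect_lt(abs(f$c - k) / k, 1e-6)
    expect_lt(abs(f$a - 7), 1e-6)
    expect_lt(abs(f$b - 8), 1e-6)
    expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  }
  # constant series: amplitude zero, rate unidentifiable
  fc <- fit_wbc_decay(t, rep(7, length(t)), 0)
  expect_equal(fc$a, 7)
  expect_equal(fc$b, 0)
  expect_true(is.na(fc$c))
  expect_equal(fc$flag, "unidentifiable")
  expect_error(fit_wbc_decay(c(0, 1, 2), c(9, 8, 7), 0), "at least 4")
})

test_that("decay fit agrees with an independent nonlinear optimizer", {
  skip_if_not_installed("minpack.lm")
  set.seed(7)
  t <- sort(runif(12, 0, 5))
  y <- (6.5 + 9 * exp(-0.8 * t)) * exp(rnorm(12, 0, 0.03))
  f <- fit_wbc_decay(t, y, 0, weighting = "none")
  nls_fit <- minpack.lm::nlsLM(y ~ a + b * exp(-c * t),
                               start = list(a = 7, b = 8, c = 1),
                               lower = c(0, 0, 0.01), upper = c(Inf, Inf, 5))
  cf <- coef(nls_fit)
  expect_equal(f$a, unname(cf["a"]), tolerance = 1e-4)
  expect_equal(f$b, unname(cf["b"]), tolerance = 1e-4)
  expect_equal(f$c, unname(cf["c"]), tolerance = 1e-4)
})

test_that("delayed linear fit locates the growth onset", {
  t <- seq(0, 5, by = 0.5)
  # flat then linear with a breakpoint at 2 days
  y <- ifelse(t < 2, 150, 150 + 25 * (t - 2))
  f <- fit_plt_growth(t, y, 0)
  expect_equal(f$tau, 2)
  expect_equal(f$f, 25, tolerance = 1e-9)
  expect_equal(f$d, 150, tolerance = 1e-9)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  # pure linear growth: smallest lag wins the tie
  f0 <- fit_plt_growth(t, 150 + 20 * t, 0)
  expect_equal(f0$tau, 0)
  expect_equal(f0$f, 20, tolerance = 1e-9)
  # constant series: zero slope, undefined adjusted R^2
  fz <- fit_plt_growth(t, rep(150, length(t)), 0)
  expect_equal(fz$f, 0)
  expect_true(is.nan(fz$adj_r2))
  expect_equal(fz$flag, "unidentifiable")
  expect_error(fit_plt_growth(c(0, 1), c(100, 110), 0), "at least 3")
})

test_that("whole-patient fit round-trips zero-noise simulated truth", {
  tr <- make_truth(k_wbc = 0.62, k_plt = 30, tau = 2.25,
                   wbc_setpoint = 9, plt_setpoint = 240)
  p <- make_model_patient("RT", tr, times = seq(0, 8, 0.5))
  f <- fit_recovery(p, "surgical")
  expect_equal(f$t_peak, 1)
  expect_lt(abs(f$c - 0.62) / 0.62, 1e-6)
  expect_lt(abs(f$a - 9) / 9, 1e-6)
  expect_lt(abs(f$b - (tr$wbc_max - 9)), 1e-6)
  # the 2.25-day breakpoint falls between 12-h samples: the lag is
  # localized to within one grid step and the slope refit stays exact
  expect_lte(abs(f$tau - 2.25), 0.25)
  expect_lt(abs(f$f - 30) / 30, 1e-6)
  expect_equal(f$half_life, log(2) / f$c)
})

test_that("dimensionless trajectories collapse onto the universal shape", {
  # two patients with different kinetics, baselines and lags
  trs <- list(make_truth(k_wbc = 0.55, k_plt = 18, tau = 1.6,
                         wbc_setpoint = 6, plt_setpoint = 150,
                         wbc_max = 17),
              make_truth(k_wbc = 0.95, k_plt = 33, tau = 2.7,
                         wbc_setpoint = 10, plt_setpoint = 300,
                         wbc_max = 16))
  for (tr in trs) {
    t <- sort(c(seq(tr$t_wbc_max, tr$t_wbc_max + 6, by = 0.25),
                tr$t_wbc_max + tr$tau))  # include the exact growth onset
    curve <- simulate_recovery_curve(tr, t)
    fit <- list(a = tr$wbc_setpoint, b = tr$wbc_max - tr$wbc_setpoint,
                c = tr$k_wbc, d = tr$plt_setpoint * (1 - tr$dip_fraction),
                f = tr$k_plt, tau = tr$tau, t_peak = tr$t_wbc_max)
    nd <- nondimensionalize(fit, t, curve$wbc, curve$plt)
    # w(t*) = exp(-t*) everywhere; w(0) = 1
    expect_lt(max(abs(nd$w - exp(-nd$t_star))), 1e-9)
    expect_equal(nd$w[1], 1, tolerance = 1e-12)
    # p(t*) = t* - tau * k in the growth phase; p = 0 at onset
    grow <- nd$t_star >= tr$tau * tr$k_wbc
    expect_lt(max(abs(nd$p[grow] - (nd$t_star[grow] - tr$tau * tr$k_wbc))),
              1e-9)
    onset <- which.min(abs(nd$t_star - tr$tau * tr$k_wbc))
    expect_lt(abs(nd$p[onset]), 1e-9)
    # closed-form spot value
    i1 <- which.min(abs(nd$t_star - 1))
    expect_equal(nd$w[i1], exp(-nd$t_star[i1]), tolerance = 1e-12)
  }
  bad <- list(a = 7, b = 0, c = 1, d = 1, f = 1, tau = 1, t_peak = 0)
  expect_error(nondimensionalize(bad, 1, 1, 1), "zero decay amplitude")
})
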