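test_that("position score counts only unfavorable deviation", {
  # WBC below and PLT above the reference contribute nothing
  expect_equal(position_score(c(0.9, 1.2), c(1.0, 1.1)), 0)
  expect_equal(position_score(c(1.5, 0.8), c(1.2, 0.9)),
               sqrt(0.3^2 + 0.1^2))
  expect_equal(position_score(c(1.2, 0.9), c(1.2, 0.9)), 0)
  expect_error(position_score(c(NA, 1), c(1, 1)), "non-finite")
  # zero iff WBC <= reference and PLT >= reference
  set.seed(11)
  for (i in 1:200) {
    p <- runif(2, 0.5, 1.5); r <- runif(2, 0.5, 1.5)
    z <- position_score(p, r)
    expect_equal(z == 0, p[1] <= r[1] && p[2] >= r[2])
  }
})

test_that("direction score is an angle with the expected symmetries", {
  expect_equal(direction_score(c(1, 1), c(2, 2)), 0, tolerance = 1e-4)
  expect_equal(direction_score(c(1, 0), c(-1, 0)), 180)
  expect_equal(direction_score(c(1, 0), c(0, 1)), 90)
  expect_true(is.na(direction_score(c(0, 0), c(1, 1))))
  set.seed(12)
  for (i in 1:100) {
    u <- rnorm(2); v <- rnorm(2); s <- runif(1, 0.1, 10)
    expect_equal(direction_score(u, v), direction_score(v, u),
                 tolerance = 1e-9)
    expect_equal(direction_score(s * u, v), direction_score(u, v),
                 tolerance = 1e-9)
    expect_gte(direction_score(u, v), 0)
    expect_lte(direction_score(u, v), 180)
  }
})

test_that("percentile transform matches a brute-force empirical CDF", {
  ref <- seq_len(101)  # 101 distinct values, median 51
  expect_equal(percentile_transform(51, ref), 50)
  expect_equal(percentile_transform(0, ref), 0)
  expect_equal(percentile_transform(101, ref), 100 * (100 + 0.5) / 101)
  set.seed(13)
  expl <- rnorm(1000)
  x <- rnorm(50)
  brute <- vapply(x, function(xi)
    100 * (sum(expl < xi) + 0.5 * sum(expl == xi)) / length(expl),
    numeric(1))
  expect_equal(percentile_transform(x, expl), brute, tolerance = 1e-12)
  expect_error(percentile_transform(1, numeric(0)), "empty")
})

test_that("strata assignment follows the joint percentile cuts", {
  df <- data.frame(position_pct = c(30, 85, 85, 55),
                   direction_pct = c(40, 90, 40, NA))
  out <- stratify(df)
  expect_equal(as.character(out$stratum),
               c("both_lt50", "both_gt80", "mixed", "mixed"))
})

test_that("relative risk reproduces printed contrasts and the Katz CI", {
  # day-5 mortality rates 17.4% vs 0.8% -> ~22x
  expect_equal(relative_risk(0.174, 0.008)$rr, 21.75)
  expect_equal(round(relative_risk(0.174, 0.008)$rr), 22)
  # day-4 adverse rates 53% vs 1.6% -> ~33x
  expect_equal(relative_risk(0.53, 0.016)$rr, 33.125)
  expect_equal(relative_risk(0.1, 0.1)$rr, 1)
  expect_true(is.infinite(relative_risk(0.2, 0)$rr))
  # Katz CI from counts: hand-computed on a small table
  rr <- relative_risk(8, 2, 40, 60)
  expect_equal(rr$rr, (8 / 40) / (2 / 60))
  se <- sqrt(1 / 8 - 1 / 40 + 1 / 2 - 1 / 60)
  expect_equal(rr$ci, exp(log(6) + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_lt(rr$ci[1], rr$rr)
  expect_gt(rr$ci[2], rr$rr)
})

test_that("2x2 chi-squared is the uncorrected Pearson statistic", {
  # perfectly proportional table: no association
  expect_equal(chi2_2x2(matrix(c(20, 40, 10, 20), 2))$statistic, 0)
  # hand computation: N (ad - bc)^2 / (r1 r2 c1 c2)
  tab <- matrix(c(10, 50, 90, 50), 2)
  hand <- 200 * (10 * 50 - 90 * 50)^2 / (100 * 100 * 60 * 140)
  out <- chi2_2x2(tab)
  expect_equal(out$statistic, hand, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("sensitivity and specificity round to the reported percentages", {
  ss <- sensitivity_specificity(29, 30, 1125, 1226)
  expect_equal(round(ss$sensitivity), 97)
  expect_equal(ss$sensitivity, 100 * 29 / 30)
  expect_equal(round(ss$specificity), 92)
  expect_equal(ss$specificity, 100 * 1125 / 1226)
  expect_equal(sensitivity_specificity(0, 10, 5, 10)$sensitivity, 0)
  # binomial CI brackets the point estimate
  expect_lt(ss$sensitivity_ci[1], ss$sensitivity)
  expect_gte(ss$sensitivity_ci[2], ss$sensitivity)
})

test_that("risk scoring flags flat days and respects the split discipline", {
  tr <- make_truth()
  good <- lapply(1:12, function(i)
    make_model_patient(paste0("G", i), tr, times = seq(0, 6, 0.5), los = 7))
  ch <- make_cohort(good)
  ref <- mean_trajectory(ch, min_n = 1)
  sc <- risk_scores(ch, ref, days = 2:5)
  # patients identical to the reference: zero position, zero angle
  expect_true(all(sc$position < 1e-9))
  expect_true(all(abs(sc$direction) < 1e-6, na.rm = TRUE))
  # a flat patient-day yields an undefined direction, not 0 degrees
  flat <- patient_record("F1", 60, "F", 1, 7, FALSE, list(
    WBC = data.frame(time = c(-1, seq(0, 6, 0.5)), value = rep(8, 14)),
    PLT = data.frame(time = c(-1, seq(0, 6, 0.5)), value = rep(200, 14))))
  sc_flat <- risk_scores(make_cohort(list(flat)), ref, days = 3)
  expect_true(is.na(sc_flat$direction))
  # percentiles computed against exploratory distributions only
  val <- assess_risk(sc, sc)
  expect_true(all(val$position_pct >= 0 & val$position_pct <= 100))
})
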