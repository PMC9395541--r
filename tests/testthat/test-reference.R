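test_that("favorable-outcome mask combines survival and LOS threshold", {
  mk <- function(id, los, dead) {
    patient_record(id, 60, "F", 1, los, dead,
                   list(WBC = data.frame(time = 0:10, value = rep(8, 11))))
  }
  ch <- make_cohort(list(mk("good", 9, FALSE), mk("died", 9, TRUE),
                         mk("long", 14, FALSE), mk("filler", 20, FALSE)))
  # mean LOS 13 -> threshold 14
  expect_equal(los_threshold(ch), 14)
  m <- good_outcome_mask(ch)
  expect_true(m[["good"]])
  expect_false(m[["died"]])
  expect_false(m[["long"]])   # LOS at the threshold is not below it
  adv <- adverse_outcome(ch)
  expect_true(adv[["died"]])
  expect_false(adv[["long"]]) # long stay means strictly above threshold
  expect_true(adv[["filler"]])
})

test_that("mean trajectory averages normalized resampled patients", {
  tr <- make_truth()
  p1 <- make_model_patient("M1", tr, times = seq(0, 6, 0.5), los = 7)
  solo <- make_cohort(list(p1, make_model_patient("M2", tr,
                                                  times = seq(0, 6, 0.5),
                                                  los = 7)))
  ref1 <- mean_trajectory(solo, mask = c(TRUE, FALSE), min_n = 1)
  ref2 <- mean_trajectory(solo, mask = c(TRUE, TRUE), min_n = 1)
  # two identical patients average to the single-patient trajectory
  expect_equal(ref1$mean_wbc_norm, ref2$mean_wbc_norm, tolerance = 1e-12)
  expect_equal(ref1$mean_plt_norm, ref2$mean_plt_norm, tolerance = 1e-12)
  # single patient: its own normalized series (baseline 7 and 200)
  curve <- simulate_recovery_curve(tr, ref1$grid)
  expect_equal(ref1$mean_wbc_norm, curve$wbc / 7, tolerance = 1e-9)
  expect_equal(ref1$mean_plt_norm, curve$plt / 200, tolerance = 1e-9)
  expect_error(mean_trajectory(solo, mask = c(FALSE, FALSE)), "no patients")
})

test_that("mean trajectory is invariant to patient order", {
  trs <- list(make_truth(k_wbc = 0.6), make_truth(k_wbc = 0.9),
              make_truth(wbc_setpoint = 9, wbc_max = 14))
  ps <- lapply(seq_along(trs), function(i)
    make_model_patient(paste0("O", i), trs[[i]], times = seq(0, 6, 0.5),
                       los = 7))
  a <- mean_trajectory(make_cohort(ps), min_n = 1)
  b <- mean_trajectory(make_cohort(rev(ps)), min_n = 1)
  expect_equal(a$mean_wbc_norm, b$mean_wbc_norm, tolerance = 1e-12)
  expect_equal(a$n_contributing, b$n_contributing)
})

test_that("zero-noise common-parameter cohort matches the analytic curve", {
  tr <- make_truth()
  ps <- lapply(1:12, function(i)
    make_model_patient(paste0("C", i), tr, times = seq(0, 6, 0.5), los = 7))
  ref <- mean_trajectory(make_cohort(ps), mask = rep(TRUE, 12), min_n = 10)
  curve <- simulate_recovery_curve(tr, ref$grid)
  expect_lt(max(abs(ref$mean_wbc_norm - curve$wbc / 7)), 1e-9)
  expect_lt(max(abs(ref$mean_plt_norm - curve$plt / 200)), 1e-9)
  expect_true(all(ref$n_contributing >= 10))
})

test_that("directional bands are ordered and degenerate correctly", {
  tr <- make_truth()
  ps <- lapply(1:12, function(i)
    make_model_patient(paste0("D", i), tr, times = seq(0, 6, 0.5), los = 7))
  ch <- make_cohort(ps)
  ref <- mean_trajectory(ch, min_n = 1)
  ref <- direction_bands(ch, reference = ref, days = 2:5)
  # every patient moves exactly along the reference: all bands at 0 degrees
  expect_true(all(abs(ref$bands$angle) < 1e-6))
  # bands non-decreasing in percentile at every day (heterogeneous cohort)
  set.seed(5)
  trs <- lapply(1:15, function(i)
    make_truth(k_wbc = runif(1, 0.5, 1), k_plt = runif(1, 15, 35),
               tau = runif(1, 1, 3)))
  ps2 <- lapply(seq_along(trs), function(i)
    make_model_patient(paste0("H", i), trs[[i]], times = seq(0, 6, 0.5),
                       los = 7))
  ch2 <- make_cohort(ps2)
  ref2 <- mean_trajectory(ch2, min_n = 1)
  ref2 <- direction_bands(ch2, reference = ref2, days = 2:5)
  for (d in unique(ref2$bands$day)) {
    ang <- ref2$bands$angle[ref2$bands$day == d]
    expect_true(all(diff(ang) >= -1e-12))
  }
})

test_that("reference trajectories survive CSV serialization", {
  tr <- make_truth()
  ps <- lapply(1:3, function(i)
    make_model_patient(paste0("S", i), tr, times = seq(0, 6, 0.5), los = 7))
  ch <- make_cohort(ps)
  ref <- direction_bands(ch, reference = mean_trajectory(ch, min_n = 1),
                         days = 2:4)
  path <- tempfile(fileext = ".csv")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(back$grid, ref$grid)
  expect_equal(back$mean_plt_norm, ref$mean_plt_norm, tolerance = 1e-9)
  expect_equal(back$bands$angle, ref$bands$angle, tolerance = 1e-9)
})
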