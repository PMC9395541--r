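test_that("cohort CSV round-trip preserves series and metadata", {
  gen <- generate_cohort(sim_config(n_patients = 4, seed = 12))
  sp <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  write_cohort(gen$cohort, sp, pp)
  back <- read_cohort(sp, pp, "surgical")
  expect_equal(n_patients(back), 4)
  p0 <- gen$cohort$patients[["P0002"]]
  p1 <- back$patients[["P0002"]]
  expect_equal(p1$series$WBC$value, p0$series$WBC$value, tolerance = 1e-9)
  expect_equal(p1$los, p0$los, tolerance = 1e-9)
  expect_equal(p1$death30, p0$death30)
})

test_that("reader resolves duplicates first-wins and flags bad files", {
  sp <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,analyte,time_days,value,units",
               "A,WBC,-1,6,10^3/uL",
               "A,WBC,0,10,10^3/uL",
               "A,WBC,0,12,10^3/uL",
               "A,WBC,1,8,10^3/uL",
               "A,WBC,2,NA,10^3/uL"), sp)
  writeLines(c("patient_id,age,gender,event_date,los,death30",
               "A,70,M,1,5,FALSE"), pp)
  expect_message(ch <- read_cohort(sp, pp), "dropped 1 rows")
  s <- ch$patients[["A"]]$series$WBC
  expect_equal(nrow(s), 3)
  expect_equal(s$value[s$time == 0], 10)  # first value wins
  # missing required column -> format error
  writeLines(c("patient_id,analyte,time_days,units",
               "A,WBC,0,10^3/uL"), sp)
  expect_error(read_cohort(sp, pp), "missing required column")
})

test_that("12-h resampling interpolates linearly without extrapolation", {
  s <- data.frame(time = c(0, 1), value = c(10, 20))
  r <- resample_12h(s)
  expect_equal(r$value[r$time == 0.5], 15)
  expect_equal(range(r$time), c(0, 1))
  # idempotent on gridded input
  expect_equal(resample_12h(r), r)
  # single observation: returned as-is, no extrapolation
  one <- resample_12h(data.frame(time = 0.3, value = 9))
  expect_equal(nrow(one), 1)
  expect_equal(one$value, 9)
  expect_error(resample_12h(data.frame(time = numeric(0),
                                       value = numeric(0))), "empty")
})

test_that("baseline mean averages pre-event draws with post-event fallback", {
  p <- patient_record("B", 60, "F", 1, 6, FALSE,
                      list(WBC = data.frame(time = c(-2, -1, 0.5),
                                            value = c(6, 8, 12))))
  expect_equal(baseline_mean(p, "WBC"), 7)
  p2 <- patient_record("B2", 60, "F", 1, 6, FALSE,
                       list(WBC = data.frame(time = c(0.5, 1),
                                             value = c(9, 12))))
  expect_equal(baseline_mean(p2, "WBC"), 9)
  p3 <- patient_record("B3", 60, "F", 1, 6, FALSE,
                       list(WBC = data.frame(time = -1, value = 7)))
  expect_equal(baseline_mean(p3, "WBC"), 7)
  expect_error(baseline_mean(p3, "PLT"), "no PLT")
})

test_that("cohort exclusions remove minors, short stays and sparse CBCs", {
  mk <- function(id, age, los, n_wbc) {
    patient_record(id, age, "M", 1, los, FALSE,
                   list(WBC = data.frame(time = seq_len(n_wbc) - 1,
                                         value = rep(8, n_wbc))))
  }
  ch <- make_cohort(list(mk("ok", 40, 5, 4), mk("young", 17, 5, 4),
                         mk("short", 40, 1.5, 4), mk("sparse", 40, 5, 1)))
  out <- apply_exclusions(ch)
  expect_equal(sort(names(out$patients)), "ok")
  counts <- attr(out, "exclusion_counts")
  expect_equal(unname(counts["age_under_18"]), 1L)
  expect_equal(unname(counts["los_under_2d"]), 1L)
  expect_equal(unname(counts["fewer_than_2_cbc"]), 1L)
  # never increases cohort size; idempotent
  expect_lte(n_patients(out), n_patients(ch))
  expect_equal(names(apply_exclusions(out)$patients), names(out$patients))
})

test_that("peak WBC search windows depend on cohort class and mode", {
  p <- patient_record("W", 60, "M", 1, 8, FALSE,
                      list(WBC = data.frame(time = c(0, 1, 2, 5),
                                            value = c(12, 16, 14, 18))))
  # surgical: 3-day window, day-5 value ignored
  expect_equal(find_peak_wbc(p, "surgical", "modeling"), 1)
  # infectious in modeling mode: whole stay
  expect_equal(find_peak_wbc(p, "infectious", "modeling"), 5)
  # infectious in risk mode: first 72 h
  expect_equal(find_peak_wbc(p, "infectious", "risk"), 1)
  # ties break to the earliest time
  p2 <- patient_record("W2", 60, "M", 1, 8, FALSE,
                       list(WBC = data.frame(time = c(1, 2),
                                             value = c(16, 16))))
  expect_equal(find_peak_wbc(p2, "surgical", "modeling"), 1)
  p3 <- patient_record("W3", 60, "M", 1, 8, FALSE,
                       list(WBC = data.frame(time = -1, value = 9)))
  expect_error(find_peak_wbc(p3, "surgical"), "window")
})

test_that("modeling subset enforces the rise and follow-up rules", {
  tr_small <- make_truth(wbc_max = 8.5)            # rise 1.5 units
  tr_ok <- make_truth(wbc_max = 13)                # rise 6 units
  ch <- make_cohort(list(
    make_model_patient("rise15", tr_small),
    make_model_patient("short", tr_ok, times = seq(0, 5.9, 0.5), los = 6),
    make_model_patient("good", tr_ok, times = seq(0, 8, 0.5))))
  out <- modeling_subset(ch)
  expect_equal(names(out$patients), "good")
  ex <- attr(out, "modeling_exclusions")
  expect_equal(unname(ex["rise_below_2"]), 1L)
  expect_equal(unname(ex["under_5d_postpeak"]), 1L)
})

test_that("long-stay threshold follows the cohort mean LOS rule", {
  mk <- function(id, los) patient_record(id, 60, "F", 1, los, FALSE,
                                         list(WBC = data.frame(time = 0:3,
                                                               value = 8:11)))
  short_stay <- make_cohort(lapply(1:4, function(i) mk(paste0("s", i), 4)))
  long_stay <- make_cohort(lapply(1:4, function(i) mk(paste0("l", i), 9)))
  expect_equal(los_threshold(short_stay), 10)
  expect_equal(los_threshold(long_stay), 14)
})
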