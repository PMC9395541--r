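# In-code fixtures shared across test files.

# a ground-truth parameter list with overridable fields
make_truth <- function(...) {
  tr <- list(wbc_setpoint = 7, plt_setpoint = 200, wbc_max = 15,
             t_wbc_max = 1, ramp_days = 1, k_wbc = 0.75, k_plt = 25,
             tau = 2, dip_fraction = 0.3, plt_cap = Inf,
             mode = NA_character_)
  over <- list(...)
  tr[names(over)] <- over
  tr
}

# a patient whose series are exact model evaluations at the given times
make_model_patient <- function(id = "X1", truth = make_truth(),
                               times = seq(0, 8, by = 0.5),
                               pre_times = c(-2, -1),
                               age = 60, los = 9, death30 = FALSE) {
  all_t <- c(pre_times, times)
  curve <- simulate_recovery_curve(truth, all_t)
  patient_record(id = id, age = age, gender = "F", event_date = 1,
                 los = los, death30 = death30,
                 series = list(WBC = data.frame(time = all_t,
                                                value = curve$wbc),
                               PLT = data.frame(time = all_t,
                                                value = curve$plt)))
}

# a minimal cohort from a list of patients
make_cohort <- function(patients, cohort_class = "surgical") {
  names(patients) <- vapply(patients, function(p) p$id, character(1))
  recovery_cohort(patients, cohort_class)
}

# two well-separated gaussian blobs for clustering tests
make_blobs <- function(n1 = 100, n2 = 100, p = 10, sep = 6, seed = 99) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p), n1),
             matrix(rnorm(n2 * p, mean = sep), n2))
  rownames(x) <- sprintf("B%03d", seq_len(n1 + n2))
  structure(x, held_out = rep(FALSE, n1 + n2),
            truth = rep(1:2, c(n1, n2)))
}
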