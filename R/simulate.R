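#' @importFrom stats rnorm runif rlnorm rbinom approx quantile median sd cor
NULL

# truncated-normal draw by rejection; cheap at the truncation levels used here
rtnorm1 <- function(mean, sd, lower) {
  if (sd == 0) return(max(mean, lower))
  repeat {
    x <- rnorm(1L, mean, sd)
    if (x >= lower) return(x)
  }
}

# auxiliary markers: baseline mean/sd and AR(1) persistence used to exercise
# the cluster-explorer filtering rules (not mechanistic models)
aux_marker_defs <- function() {
  list(
    HCT   = list(mean = 38.1, sd = 6.1),
    RDW   = list(mean = 14.2, sd = 2.2),
    ANION = list(mean = 12,   sd = 3),
    BUN   = list(mean = 18,   sd = 7),
    CRE   = list(mean = 1.0,  sd = 0.3),
    GLU   = list(mean = 110,  sd = 30)
  )
}

analyte_units <- function(analyte) {
  switch(analyte,
         WBC = "10^3/uL", PLT = "10^3/uL", HCT = "%", HGB = "g/dL",
         RBC = "10^6/uL", RDW = "%", ANION = "mmol/L", BUN = "mg/dL",
         CRE = "mg/dL", GLU = "mg/dL", "arbitrary")
}

# Draw one patient's ground-truth kinetic parameters from the config.
draw_truth <- function(cfg, id) {
  wbc_set <- rtnorm1(cfg$baseline_wbc_mean, cfg$baseline_wbc_sd, 2)
  plt_set <- rtnorm1(cfg$baseline_plt_mean, cfg$baseline_plt_sd, 80)
  muted <- runif(1L) < cfg$muted_wbc_fraction
  rise <- if (muted) runif(1L, 0.2, 1.5) else
    rtnorm1(cfg$peak_rise_mean, cfg$peak_rise_sd, 2.5)
  t_peak <- runif(1L, cfg$t_peak_range[1], cfg$t_peak_range[2])
  ramp <- min(runif(1L, cfg$ramp_days_range[1], cfg$ramp_days_range[2]), t_peak)
  k_wbc <- runif(1L, cfg$k_wbc_range[1], cfg$k_wbc_range[2])
  k_plt <- runif(1L, cfg$k_plt_range[1], cfg$k_plt_range[2])
  tau <- rtnorm1(cfg$tau_delay_mean, cfg$tau_delay_sd, 0)

  adverse <- !muted && runif(1L) < cfg$adverse_fraction
  mode <- NA_character_
  onset <- NA_real_
  magnitude <- 0
  rebound_amp <- NA_real_
  decline_rate <- NA_real_
  if (adverse) {
    mode <- sample(names(cfg$adverse_modes), 1L, prob = cfg$adverse_modes)
    onset <- t_peak + runif(1L, 0.5, 2.0)
    if (mode == "wbc_rebound") {
      rebound_amp <- runif(1L, 4, 10)
      magnitude <- rebound_amp / 7
    } else if (mode == "plt_decline") {
      decline_rate <- runif(1L, 10, 30)
      magnitude <- decline_rate / 20
    } else { # stalled_recovery: decay rate shrunk x0.2 after onset
      magnitude <- 1
    }
  }

  list(id = id,
       wbc_setpoint = wbc_set, plt_setpoint = plt_set,
       wbc_max = wbc_set + rise, t_wbc_max = t_peak,
       ramp_days = ramp,
       k_wbc = k_wbc, k_plt = k_plt, tau = tau,
       dip_fraction = cfg$plt_dip_fraction,
       plt_cap = plt_set * (1 + cfg$overshoot_fraction),
       muted = muted,
       outcome = if (adverse) "adverse" else "good",
       mode = mode, onset = onset, magnitude = magnitude,
       rebound_amp = rebound_amp, decline_rate = decline_rate)
}

#' Evaluate the noiseless recovery model for one patient
#'
#' Computes WBC and PLT (10^3/uL) at the requested times from a
#' ground-truth parameter record. After the WBC peak at
#' \code{t_wbc_max}, WBC decays exponentially toward the setpoint:
#' \code{setpoint + (max - setpoint) * exp(-k_wbc * (t - t_wbc_max))}.
#' PLT stays at its dipped level until \code{t_wbc_max + tau}, then grows
#' linearly with slope \code{k_plt}, capped at \code{plt_cap} (the
#' setpoint times one plus the overshoot fraction; \code{Inf} disables the
#' cap). Before the peak, WBC rises linearly from the setpoint over
#' \code{ramp_days} and PLT dips linearly from the setpoint (from the
#' event at t = 0) to \code{setpoint * (1 - dip_fraction)} at the peak.
#' Pre-event times (t < 0) return the setpoints.
#'
#' @param truth a ground-truth record as produced by
#'   \code{\link{generate_cohort}} (one row of the truth table, as a list
#'   or one-row data.frame).
#' @param times numeric vector of days relative to the event, sorted.
#' @param divergence apply the record's adverse-mode distortion (if any).
#' @return data.frame with columns \code{time}, \code{wbc}, \code{plt}.
#' @export
#' @examples
#' tr <- list(wbc_setpoint = 7, plt_setpoint = 200, wbc_max = 15,
#'            t_wbc_max = 1, ramp_days = 1, k_wbc = 0.75, k_plt = 25,
#'            tau = 2, dip_fraction = 0.3, plt_cap = Inf,
#'            mode = NA_character_)
#' simulate_recovery_curve(tr, c(1, 1 + log(2) / 0.75))
simulate_recovery_curve <- function(truth, times, divergence = TRUE) {
  truth <- as.list(truth)
  pars <- c("wbc_setpoint", "plt_setpoint", "wbc_max", "t_wbc_max",
            "ramp_days", "k_wbc", "k_plt", "tau", "dip_fraction")
  vals <- unlist(truth[pars])
  if (any(!is.finite(vals)))
    stop("non-finite truth parameters: ",
         paste(pars[!is.finite(vals)], collapse = ", "))
  if (is.unsorted(times)) stop("`times` must be sorted")

  tp <- truth$t_wbc_max
  ramp_start <- tp - truth$ramp_days
  wbc <- numeric(length(times))
  plt <- numeric(length(times))

  pre <- times < ramp_start
  ramp <- times >= ramp_start & times < tp
  post <- times >= tp
  wbc[pre] <- truth$wbc_setpoint
  wbc[ramp] <- truth$wbc_setpoint +
    (truth$wbc_max - truth$wbc_setpoint) *
    (times[ramp] - ramp_start) / truth$ramp_days
  wbc[post] <- truth$wbc_setpoint +
    (truth$wbc_max - truth$wbc_setpoint) *
    exp(-truth$k_wbc * (times[post] - tp))

  dipped <- truth$plt_setpoint * (1 - truth$dip_fraction)
  t_break <- tp + truth$tau
  plt[times < 0] <- truth$plt_setpoint
  dip_phase <- times >= 0 & times < tp
  plt[dip_phase] <- truth$plt_setpoint -
    (truth$plt_setpoint - dipped) * times[dip_phase] / max(tp, 1e-9)
  flat <- times >= tp & times < t_break
  plt[flat] <- dipped
  grow <- times >= t_break
  cap <- if (is.null(truth$plt_cap) || is.na(truth$plt_cap)) Inf else truth$plt_cap
  plt[grow] <- pmin(dipped + truth$k_plt * (times[grow] - t_break), cap)

  if (isTRUE(divergence) && !is.null(truth$mode) && !is.na(truth$mode)) {
    on <- truth$onset
    late <- times >= on
    if (truth$mode == "wbc_rebound") {
      wbc[late] <- wbc[late] +
        truth$rebound_amp * (1 - exp(-0.8 * (times[late] - on)))
    } else if (truth$mode == "plt_decline") {
      plt_on <- simulate_recovery_curve(truth, on, divergence = FALSE)$plt
      plt[late] <- pmax(plt_on - truth$decline_rate * (times[late] - on), 20)
    } else if (truth$mode == "stalled_recovery") {
      wbc_on <- truth$wbc_setpoint +
        (truth$wbc_max - truth$wbc_setpoint) * exp(-truth$k_wbc * (on - tp))
      stall <- late & times >= tp
      wbc[stall] <- truth$wbc_setpoint + (wbc_on - truth$wbc_setpoint) *
        exp(-0.2 * truth$k_wbc * (times[stall] - on))
    }
  }
  data.frame(time = times, wbc = wbc, plt = plt)
}

# lognormal multiplicative noise with unit mean and coefficient of variation cv
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate one patient record
#'
#' Samples the noiseless recovery curve at irregular times (successive
#' gaps uniform within \code{sampling_interval_hours}), applies
#' multiplicative lognormal measurement noise, injects the adverse-mode
#' distortion for divergent patients, draws a discharge time (the larger
#' of the model recovery time and a lognormal length-of-stay draw, at
#' least 2 days), censors measurements after discharge, and assigns
#' outcome labels. Auxiliary markers (HCT, HGB, RBC, RDW, ANION, BUN,
#' CRE, GLU) are generated as noisy AR(1) deviations around baseline; HGB
#' and RBC track HCT closely so the red-cell collapse rule is exercised.
#'
#' Uses the current R random-number state; seed the session (or call via
#' \code{\link{generate_cohort}}, which seeds from the config) for
#' reproducibility.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param id patient identifier.
#' @param event_date numeric date index (days) used for the
#'   exploratory/validation split ordering.
#' @return list with elements \code{patient} (a \code{patient_record}) and
#'   \code{truth} (named list of ground-truth parameters).
#' @export
simulate_patient <- function(cfg, id = "P1", event_date = 0) {
  validate_sim_config(cfg)
  truth <- draw_truth(cfg, id)

  # length of stay: at least model recovery time, at least 2 days
  recovery_time <- truth$t_wbc_max + 3 / truth$k_wbc
  base_los <- rlnorm(1L, cfg$los_meanlog, cfg$los_sdlog)
  if (truth$outcome == "adverse") {
    los <- max(base_los, 10) + runif(1L, 5, 20)
    death30 <- runif(1L) < stats::plogis(-2 + 1.5 * truth$magnitude)
  } else {
    los <- max(base_los, recovery_time, 2.1)
    death30 <- FALSE
  }
  los <- max(los, 2.1)
  truth$los <- los
  truth$death30 <- death30

  # irregular sampling: pre-event baseline draws plus in-stay draws
  pre_t <- sort(-runif(cfg$n_pre_draws, 0.2, 3))
  horizon <- min(los, 30)
  gaps <- cfg$sampling_interval_hours / 24
  t <- runif(1L, 0.05, 0.3)
  post_t <- t
  while (TRUE) {
    t <- t + runif(1L, gaps[1], gaps[2])
    if (t > horizon) break
    post_t <- c(post_t, t)
  }
  # the inflammatory peak triggers a draw: blood counts are checked when
  # the patient looks worst, and peak alignment assumes the peak is seen
  if (truth$t_wbc_max <= horizon) post_t <- c(post_t, truth$t_wbc_max)
  times <- sort(c(pre_t, post_t))

  curve <- simulate_recovery_curve(truth, times)
  wbc <- curve$wbc * ln_noise(length(times), cfg$noise_cv)
  plt <- curve$plt * ln_noise(length(times), cfg$noise_cv)

  series <- list(
    WBC = data.frame(time = times, value = pmax(wbc, 0.05)),
    PLT = data.frame(time = times, value = pmax(plt, 1))
  )

  # auxiliary markers: AR(1) around a patient-level baseline
  defs <- aux_marker_defs()
  for (mk in names(defs)) {
    base <- rtnorm1(defs[[mk]]$mean, defs[[mk]]$sd, 0.2 * defs[[mk]]$mean)
    n <- length(times)
    dev <- numeric(n)
    sig <- 0.05 * base
    dev[1] <- rnorm(1L, 0, sig)
    if (n > 1) for (i in 2:n) dev[i] <- 0.7 * dev[i - 1] + rnorm(1L, 0, sig)
    series[[mk]] <- data.frame(time = times, value = pmax(base + dev, 0.01))
  }
  hct <- series$HCT$value
  series$HGB <- data.frame(time = times,
                           value = hct / 3 + rnorm(length(times), 0, 0.15))
  series$RBC <- data.frame(time = times,
                           value = hct / 11.4 + rnorm(length(times), 0, 0.04))

  patient <- patient_record(
    id = id,
    age = round(min(max(rnorm(1L, 63.9, 13), 18), 95)),
    gender = if (runif(1L) < 0.713) "M" else "F",
    event_date = event_date,
    los = los,
    death30 = death30,
    series = series
  )
  list(patient = patient, truth = truth)
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates \code{cfg$n_patients} patients (seeded from \code{cfg$seed},
#' so output is fully reproducible) and returns the cohort together with
#' the ground-truth parameter table. Event dates are sequential, so
#' \code{\link{split_cohort}} reproduces an earlier-half/later-half
#' exploratory/validation partition.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with elements \code{cohort} (a \code{recovery_cohort}) and
#'   \code{truth} (data.frame, one row per patient).
#' @export
#' @examples
#' out <- generate_cohort(sim_config(n_patients = 3, seed = 7))
#' out$truth$k_wbc
generate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  ids <- sprintf("P%04d", seq_len(cfg$n_patients))
  patients <- vector("list", cfg$n_patients)
  truth_rows <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    sim <- simulate_patient(cfg, id = ids[i], event_date = i)
    patients[[i]] <- sim$patient
    tr <- sim$truth
    tr$rebound_amp <- if (is.na(tr$rebound_amp)) NA_real_ else tr$rebound_amp
    truth_rows[[i]] <- as.data.frame(tr, stringsAsFactors = FALSE)
  }
  names(patients) <- ids
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  cohort <- recovery_cohort(patients, cohort_class = cfg$cohort_class)
  list(cohort = cohort, truth = truth)
}

#' Split a cohort into exploratory and validation halves by event date
#'
#' Patients are ordered by event date and split evenly; the earlier half
#' forms the exploratory set (used to build references and percentile
#' thresholds) and the later half the validation set (used to report
#' out-of-sample risk).
#'
#' @param cohort a \code{recovery_cohort}.
#' @return list with \code{recovery_cohort} elements \code{exploratory}
#'   and \code{validation}.
#' @export
split_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "recovery_cohort"))
  dates <- vapply(cohort$patients, function(p) p$event_date, numeric(1))
  ord <- names(sort(dates))
  n <- length(ord)
  n_exp <- ceiling(n / 2)
  val_ids <- if (n_exp < n) ord[(n_exp + 1):n] else character(0)
  list(
    exploratory = recovery_cohort(cohort$patients[ord[seq_len(n_exp)]],
                                  cohort$cohort_class),
    validation = recovery_cohort(cohort$patients[val_ids],
                                 cohort$cohort_class)
  )
}
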