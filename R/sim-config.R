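#' Simulation configuration for synthetic inflammatory-recovery cohorts
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults
#' emulate a non-emergency cardiac-surgery cohort: baseline setpoints drawn
#' around the cardiac cohort means (WBC 7.9 (3.1), PLT 217.9 (71.7), both
#' 10^3 cells/uL), a post-event WBC peak within the first 2.5 days, a PLT
#' dip of ~30% at the peak, exponential WBC decay with rate in
#' [0.5, 1.0]/day, PLT growth starting ~2 days after the WBC peak with a
#' possible overshoot of the setpoint, multiplicative lognormal measurement
#' noise (CV 3%), irregular 12-24 h sampling, discharge censoring, and an
#' adverse subpopulation with divergent dynamics.
#'
#' @param n_patients number of patients to simulate.
#' @param cohort_class one of \code{"surgical"}, \code{"ischemic"},
#'   \code{"infectious"}; controls peak-alignment windows downstream.
#' @param baseline_wbc_mean,baseline_wbc_sd WBC setpoint distribution
#'   (10^3/uL), truncated below at 2.
#' @param baseline_plt_mean,baseline_plt_sd PLT setpoint distribution
#'   (10^3/uL), truncated below at 80.
#' @param peak_rise_mean,peak_rise_sd WBC excess at peak over the setpoint
#'   (10^3/uL), truncated below at 2.5 for non-muted patients so the
#'   modeling-inclusion rise rule is informative.
#' @param k_wbc_range WBC decay-rate interval (1/day), default [0.5, 1.0].
#' @param k_plt_range PLT growth-slope interval (10^3/(uL day)).
#' @param tau_delay_mean,tau_delay_sd PLT growth lag after peak WBC (days),
#'   normal truncated at 0; default 2.0 (0.3).
#' @param plt_dip_fraction fractional PLT dip from setpoint at peak WBC,
#'   in [0, 1).
#' @param overshoot_fraction PLT growth is capped at
#'   \code{setpoint * (1 + overshoot_fraction)}; use \code{Inf} for no cap.
#' @param noise_cv multiplicative measurement-noise coefficient of
#'   variation; 0 disables noise.
#' @param sampling_interval_hours two-element interval; successive draws
#'   are separated by a uniform draw from it (default [12, 24] h).
#' @param t_peak_range interval (days after event) for the true WBC peak.
#' @param ramp_days_range interval (days) for the linear pre-peak WBC rise.
#' @param adverse_fraction fraction of patients given divergent dynamics.
#' @param adverse_modes named weights over
#'   \code{c("wbc_rebound","plt_decline","stalled_recovery")}.
#' @param muted_wbc_fraction fraction of patients whose WBC rise is < 2
#'   units (muted inflammatory response).
#' @param los_meanlog,los_sdlog lognormal length-of-stay draw (days); the
#'   realized stay is at least the model recovery time and at least 2 days.
#' @param n_pre_draws number of pre-event baseline draws per patient.
#' @param seed integer seed; fully determines \code{\link{generate_cohort}}
#'   output.
#'
#' @return an object of class \code{sim_config} (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 5, seed = 1)
#' cfg$baseline_wbc_mean
sim_config <- function(n_patients = 100L,
                       cohort_class = c("surgical", "ischemic", "infectious"),
                       baseline_wbc_mean = 7.9, baseline_wbc_sd = 3.1,
                       baseline_plt_mean = 217.9, baseline_plt_sd = 71.7,
                       peak_rise_mean = 8.0, peak_rise_sd = 2.5,
                       k_wbc_range = c(0.5, 1.0),
                       k_plt_range = c(15, 35),
                       tau_delay_mean = 2.0, tau_delay_sd = 0.3,
                       plt_dip_fraction = 0.3,
                       overshoot_fraction = 0.5,
                       noise_cv = 0.03,
                       sampling_interval_hours = c(12, 24),
                       t_peak_range = c(0.5, 2.5),
                       ramp_days_range = c(0.5, 2.0),
                       adverse_fraction = 0.1,
                       adverse_modes = c(wbc_rebound = 1, plt_decline = 1,
                                         stalled_recovery = 1),
                       muted_wbc_fraction = 0.005,
                       los_meanlog = log(6), los_sdlog = 0.5,
                       n_pre_draws = 2L,
                       seed = 1L) {
  cohort_class <- match.arg(cohort_class)
  cfg <- list(
    n_patients = as.integer(n_patients), cohort_class = cohort_class,
    baseline_wbc_mean = baseline_wbc_mean, baseline_wbc_sd = baseline_wbc_sd,
    baseline_plt_mean = baseline_plt_mean, baseline_plt_sd = baseline_plt_sd,
    peak_rise_mean = peak_rise_mean, peak_rise_sd = peak_rise_sd,
    k_wbc_range = k_wbc_range, k_plt_range = k_plt_range,
    tau_delay_mean = tau_delay_mean, tau_delay_sd = tau_delay_sd,
    plt_dip_fraction = plt_dip_fraction,
    overshoot_fraction = overshoot_fraction,
    noise_cv = noise_cv,
    sampling_interval_hours = sampling_interval_hours,
    t_peak_range = t_peak_range, ramp_days_range = ramp_days_range,
    adverse_fraction = adverse_fraction,
    adverse_modes = adverse_modes / sum(adverse_modes),
    muted_wbc_fraction = muted_wbc_fraction,
    los_meanlog = los_meanlog, los_sdlog = los_sdlog,
    n_pre_draws = as.integer(n_pre_draws),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_patients >= 1L,
    cfg$baseline_wbc_mean > 0, cfg$baseline_plt_mean > 0,
    cfg$baseline_wbc_sd >= 0, cfg$baseline_plt_sd >= 0,
    length(cfg$k_wbc_range) == 2L, all(cfg$k_wbc_range > 0),
    diff(cfg$k_wbc_range) >= 0,
    length(cfg$k_plt_range) == 2L, all(cfg$k_plt_range > 0),
    cfg$tau_delay_mean >= 0, cfg$tau_delay_sd >= 0,
    cfg$plt_dip_fraction >= 0, cfg$plt_dip_fraction < 1,
    cfg$overshoot_fraction >= 0,
    cfg$noise_cv >= 0,
    length(cfg$sampling_interval_hours) == 2L,
    all(cfg$sampling_interval_hours > 0),
    cfg$adverse_fraction >= 0, cfg$adverse_fraction <= 1,
    cfg$muted_wbc_fraction >= 0, cfg$muted_wbc_fraction <= 1,
    all(names(cfg$adverse_modes) %in%
          c("wbc_rebound", "plt_decline", "stalled_recovery")),
    abs(sum(cfg$adverse_modes) - 1) < 1e-12,
    is.finite(cfg$seed)
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration (", x$cohort_class, ")\n", sep = "")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat(sprintf("  WBC setpoint %.1f (%.1f), PLT setpoint %.1f (%.1f) 10^3/uL\n",
              x$baseline_wbc_mean, x$baseline_wbc_sd,
              x$baseline_plt_mean, x$baseline_plt_sd))
  cat(sprintf("  k_wbc in [%.2f, %.2f]/d, tau %.1f (%.1f) d, noise CV %.1f%%\n",
              x$k_wbc_range[1], x$k_wbc_range[2],
              x$tau_delay_mean, x$tau_delay_sd, 100 * x$noise_cv))
  cat(sprintf("  adverse fraction %.2f, muted fraction %.3f\n",
              x$adverse_fraction, x$muted_wbc_fraction))
  invisible(x)
}
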