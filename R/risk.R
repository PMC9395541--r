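#' Positional deviation from the reference trajectory
#'
#' Euclidean distance in the normalized WBC-PLT plane between a
#' patient-day point and the reference point, counting only unfavorable
#' deviation: WBC below the reference and PLT above the reference
#' contribute zero distance.
#'
#' @param patient_point length-2 numeric \code{c(wbc, plt)} in
#'   baseline-normalized units.
#' @param reference_point length-2 numeric \code{c(wbc, plt)}.
#' @return nonnegative distance (unitless).
#' @export
#' @examples
#' position_score(c(1.5, 0.8), c(1.2, 0.9)) # sqrt(0.3^2 + 0.1^2)
#' position_score(c(0.9, 1.2), c(1.0, 1.1)) # 0
position_score <- function(patient_point, reference_point) {
  if (any(!is.finite(patient_point)) || any(!is.finite(reference_point)))
    stop("non-finite input")
  dw <- max(patient_point[1] - reference_point[1], 0)
  dp <- max(reference_point[2] - patient_point[2], 0)
  sqrt(dw^2 + dp^2)
}

#' Directional deviation from the reference trajectory
#'
#' Angle in degrees between the patient's normalized 24-h WBC-PLT change
#' vector and the reference trajectory's change vector, in [0, 180].
#' Undefined (\code{NA}) for a zero-length vector: a flat patient-day
#' carries no directional information and must not masquerade as perfect
#' alignment.
#'
#' @param patient_delta length-2 numeric change vector.
#' @param reference_delta length-2 numeric change vector.
#' @return angle in degrees, or \code{NA} if either vector is zero.
#' @export
direction_score <- function(patient_delta, reference_delta) {
  np <- sqrt(sum(patient_delta^2))
  nr <- sqrt(sum(reference_delta^2))
  if (!is.finite(np) || !is.finite(nr) || np == 0 || nr == 0)
    return(NA_real_)
  cosang <- sum(patient_delta * reference_delta) / (np * nr)
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Empirical percentile transform against an exploratory distribution
#'
#' Converts scores to percentiles of the empirical CDF of an exploratory
#' distribution, with midpoint tie handling: the percentile of x is
#' \code{100 * (#\{ref < x\} + 0.5 #\{ref = x\}) / n}.
#'
#' @param scores numeric vector to transform.
#' @param exploratory numeric reference distribution (nonempty).
#' @return percentiles in [0, 100]; \code{NA} scores stay \code{NA}.
#' @export
percentile_transform <- function(scores, exploratory) {
  exploratory <- exploratory[is.finite(exploratory)]
  if (length(exploratory) == 0) stop("empty exploratory distribution")
  sr <- sort(exploratory)
  n <- length(sr)
  out <- rep(NA_real_, length(scores))
  ok <- is.finite(scores)
  n_le <- findInterval(scores[ok], sr)
  n_lt <- findInterval(scores[ok], sr, left.open = TRUE)
  out[ok] <- 100 * (n_lt + 0.5 * (n_le - n_lt)) / n
  out
}

#' Position and direction scores for each patient-day
#'
#' For each patient and post-event day, computes the positional deviation
#' of the patient's baseline-normalized WBC-PLT point from the reference
#' trajectory and the directional deviation of the 24-h change vector
#' from the reference's change vector. In \code{"interpolated"} mode
#' (default) patient values are taken at exact 24-h gridpoints of the
#' 12-h resampled series; in \code{"raw"} mode the last two non-repeat
#' measurements at or before the day are used.
#'
#' @param cohort a \code{recovery_cohort}.
#' @param reference a \code{reference_trajectory} (its alignment is
#'   reused; infectious cohorts align on the peak WBC within 72 h).
#' @param days integer post-event days to score (default 1 to 7).
#' @param mode \code{"interpolated"} or \code{"raw"}.
#' @param mask optional logical patient selector.
#' @return data.frame with \code{patient_id}, \code{day}, \code{position},
#'   \code{direction} (degrees, \code{NA} when undefined).
#' @export
risk_scores <- function(cohort, reference, days = 1:7,
                        mode = c("interpolated", "raw"), mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "reference_trajectory"))
  patients <- cohort$patients
  if (!is.null(mask)) patients <- patients[mask]
  rows <- list()
  for (p in patients) {
    if (mode == "interpolated") {
      z <- normalized_pair(p, cohort$cohort_class, reference$alignment)
      if (is.null(z)) next
      val_at <- function(s, t) {
        i <- match(round(t * 2), round(s$time * 2))
        if (is.na(i)) NA_real_ else s$value[i]
      }
      get_point <- function(d) c(val_at(z$wbc, d), val_at(z$plt, d))
    } else {
      bw <- baseline_mean(p, "WBC"); bp <- baseline_mean(p, "PLT")
      sw <- p$series[["WBC"]]; sp <- p$series[["PLT"]]
      if (is.null(sw) || is.null(sp)) next
      last_two <- function(s, d, base) {
        v <- s$value[s$time <= d & s$time >= 0] / base
        if (length(v) > 1) v <- v[c(TRUE, diff(v) != 0)]  # drop repeats
        if (length(v) == 0) c(NA_real_, NA_real_)
        else if (length(v) == 1) c(NA_real_, v)
        else c(v[length(v) - 1], v[length(v)])
      }
      get_point <- NULL
    }
    for (d in days) {
      ref_pt <- reference_at(reference, d)
      if (any(is.na(ref_pt))) next
      if (mode == "interpolated") {
        now <- get_point(d)
        prev <- get_point(d - 1)
      } else {
        lw <- last_two(sw, d, bw); lp <- last_two(sp, d, bp)
        now <- c(lw[2], lp[2]); prev <- c(lw[1], lp[1])
      }
      if (any(is.na(now))) next
      pos <- position_score(now, ref_pt)
      dir <- NA_real_
      rd <- reference_delta(reference, d)
      if (!any(is.na(prev)) && !any(is.na(rd))) {
        dir <- direction_score(now - prev, c(rd[["dw"]], rd[["dp"]]))
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p$id, day = d, position = pos, direction = dir,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(patient_id = character(0), day = integer(0),
               position = numeric(0), direction = numeric(0))
  rownames(out) <- NULL
  out
}

#' Out-of-sample risk assessment against exploratory distributions
#'
#' Converts validation-cohort position and direction scores to
#' percentiles of the same-day exploratory distributions and assigns a
#' joint stratum. All thresholds derive only from the exploratory scores;
#' nothing from the validation cohort feeds back into them.
#'
#' @param validation_scores data.frame from \code{\link{risk_scores}} on
#'   the validation cohort.
#' @param exploratory_scores data.frame from \code{\link{risk_scores}} on
#'   the exploratory cohort.
#' @param thresholds lower/upper percentile cuts, default \code{c(50, 80)}.
#' @return the validation scores with \code{position_pct},
#'   \code{direction_pct} and \code{stratum} columns added.
#' @export
assess_risk <- function(validation_scores, exploratory_scores,
                        thresholds = c(50, 80)) {
  out <- validation_scores
  out$position_pct <- NA_real_
  out$direction_pct <- NA_real_
  for (d in unique(out$day)) {
    ev <- exploratory_scores[exploratory_scores$day == d, , drop = FALSE]
    vi <- which(out$day == d)
    if (nrow(ev) == 0) next
    out$position_pct[vi] <- percentile_transform(out$position[vi],
                                                 ev$position)
    dir_ref <- ev$direction[is.finite(ev$direction)]
    if (length(dir_ref) > 0)
      out$direction_pct[vi] <- percentile_transform(out$direction[vi],
                                                    dir_ref)
  }
  stratify(out, thresholds)
}

#' Assign joint position/direction strata
#'
#' \code{both_lt50}: position and direction percentiles both below the
#' lower threshold; \code{both_gt80}: both above the upper threshold;
#' \code{mixed}: everything else (including patient-days with an
#' undefined direction).
#'
#' @param assessments data.frame with \code{position_pct} and
#'   \code{direction_pct}.
#' @param thresholds lower/upper percentile cuts, default \code{c(50, 80)}.
#' @return the input with a \code{stratum} factor added.
#' @export
stratify <- function(assessments, thresholds = c(50, 80)) {
  lo <- thresholds[1]; hi <- thresholds[2]
  pp <- assessments$position_pct
  dp <- assessments$direction_pct
  stratum <- rep("mixed", nrow(assessments))
  both_ok <- is.finite(pp) & is.finite(dp)
  stratum[both_ok & pp < lo & dp < lo] <- "both_lt50"
  stratum[both_ok & pp > hi & dp > hi] <- "both_gt80"
  stratum[!is.finite(pp)] <- NA_character_
  assessments$stratum <- factor(stratum,
                                levels = c("both_lt50", "mixed", "both_gt80"))
  assessments
}

#' Stratum-by-outcome contingency tables per day
#'
#' @param assessments output of \code{\link{assess_risk}} (or
#'   \code{\link{stratify}}).
#' @param adverse named logical vector of adverse outcomes by patient id
#'   (see \code{\link{adverse_outcome}}).
#' @param days days to tabulate (default: all present).
#' @return named list (by day) of stratum x outcome count tables.
#' @export
strata_table <- function(assessments, adverse, days = NULL) {
  if (is.null(days)) days <- sort(unique(assessments$day))
  out <- list()
  for (d in days) {
    a <- assessments[assessments$day == d & !is.na(assessments$stratum), ,
                     drop = FALSE]
    if (nrow(a) == 0) next
    ev <- adverse[a$patient_id]
    out[[as.character(d)]] <- table(stratum = a$stratum,
                                    adverse = factor(ev, c(FALSE, TRUE)))
  }
  out
}

#' Relative risk with Katz log-normal confidence interval
#'
#' Given event counts and group sizes, RR = (a/n1) / (b/n0) with the Katz
#' 95% CI \code{exp(log RR +/- 1.96 sqrt(1/a - 1/n1 + 1/b - 1/n0))}.
#' Given two rates only, the point estimate is returned without a CI.
#'
#' @param r1 exposed-group rate, or event count \code{a} when counts are
#'   supplied.
#' @param r0 reference-group rate, or event count \code{b}.
#' @param n1,n0 group sizes (supply both to use counts).
#' @return list with \code{rr}, and \code{ci} (length-2) when counts are
#'   given. A zero reference rate yields \code{rr = Inf} with a flag.
#' @export
#' @examples
#' relative_risk(0.174, 0.008)$rr   # ~21.75, the "22x" day-5 contrast
#' relative_risk(0.53, 0.016)$rr    # ~33.1, the day-4 contrast
relative_risk <- function(r1, r0, n1 = NULL, n0 = NULL) {
  if (!is.null(n1) && !is.null(n0)) {
    a <- r1; b <- r0
    p1 <- a / n1; p0 <- b / n0
    if (p0 == 0) return(list(rr = Inf, ci = c(NA_real_, NA_real_),
                             flag = "zero_reference_rate"))
    rr <- p1 / p0
    if (a > 0 && b > 0) {
      se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
      ci <- exp(log(rr) + c(-1, 1) * stats::qnorm(0.975) * se)
    } else ci <- c(NA_real_, NA_real_)
    return(list(rr = rr, ci = ci, rates = c(p1, p0)))
  }
  if (r0 == 0) return(list(rr = Inf, flag = "zero_reference_rate"))
  list(rr = r1 / r0)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-squared test of
#' independence, df = 1.
#'
#' @param counts 2x2 matrix (or table) of nonnegative counts with
#'   positive margins.
#' @return list with \code{statistic}, \code{p}, \code{df}.
#' @export
chi2_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Sensitivity and specificity with binomial confidence intervals
#'
#' Percent of adverse events captured by a flag (sensitivity) and percent
#' of non-events correctly unflagged (specificity), each with an exact
#' Clopper-Pearson 95% CI.
#'
#' @param flagged_events number of adverse events above the flag
#'   threshold.
#' @param total_events total adverse events.
#' @param true_negatives number of non-events below the threshold.
#' @param total_nonevents total non-events.
#' @return list with \code{sensitivity}, \code{specificity} (percent) and
#'   their CIs (percent).
#' @export
#' @examples
#' sensitivity_specificity(29, 30, 1125, 1226)
sensitivity_specificity <- function(flagged_events, total_events,
                                    true_negatives, total_nonevents) {
  stopifnot(total_events > 0, total_nonevents > 0)
  se_ci <- stats::binom.test(flagged_events, total_events)$conf.int
  sp_ci <- stats::binom.test(true_negatives, total_nonevents)$conf.int
  list(sensitivity = 100 * flagged_events / total_events,
       sensitivity_ci = 100 * as.numeric(se_ci),
       specificity = 100 * true_negatives / total_nonevents,
       specificity_ci = 100 * as.numeric(sp_ci))
}
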