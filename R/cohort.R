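#' Construct a patient record
#'
#' One patient's demographics, event/discharge information, outcome labels
#' and laboratory series. Times are real-valued days relative to the
#' inflammatory event (surgery end or admission); pre-event times are
#' negative. Each series is a data.frame with columns \code{time} and
#' \code{value}, sorted by time with duplicate timestamps resolved
#' first-wins.
#'
#' @param id patient identifier (character).
#' @param age years.
#' @param gender character (\code{"M"}/\code{"F"} or other coding).
#' @param event_date numeric or date-like ordering key for the
#'   exploratory/validation split.
#' @param los length of stay in days; discharge time on the event axis.
#' @param death30 logical, all-cause mortality within 30 days.
#' @param series named list of data.frames (\code{time}, \code{value}),
#'   one per analyte code (WBC, PLT, HCT, ...). WBC and PLT are in
#'   10^3 cells/uL.
#' @return object of class \code{patient_record}.
#' @export
patient_record <- function(id, age, gender, event_date, los, death30, series) {
  stopifnot(is.list(series), length(names(series)) == length(series))
  series <- lapply(series, clean_series)
  x <- list(id = as.character(id), age = age, gender = gender,
            event_date = event_date, los = los,
            discharge_time = los, death30 = isTRUE(death30),
            series = series)
  class(x) <- "patient_record"
  x
}

# sort by time, drop non-finite values, resolve duplicate timestamps
# first-wins (order of appearance)
clean_series <- function(df) {
  stopifnot(all(c("time", "value") %in% names(df)))
  keep <- is.finite(df$time) & is.finite(df$value)
  df <- df[keep, c("time", "value"), drop = FALSE]
  df <- df[!duplicated(df$time), , drop = FALSE]
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.patient_record <- function(x, ...) {
  cat("Patient", x$id, "- age", x$age, x$gender,
      "- LOS", sprintf("%.1f d", x$los),
      if (x$death30) "- died <30 d" else "", "\n")
  cat("  analytes:",
      paste(sprintf("%s(%d)", names(x$series),
                    vapply(x$series, nrow, integer(1))), collapse = " "), "\n")
  invisible(x)
}

#' Construct a cohort of patient records
#'
#' @param patients named list of \code{patient_record}s (names = ids).
#' @param cohort_class one of \code{"surgical"}, \code{"ischemic"},
#'   \code{"infectious"}; determines the peak-WBC alignment window and the
#'   long-LOS threshold rule downstream.
#' @return object of class \code{recovery_cohort}.
#' @export
recovery_cohort <- function(patients,
                            cohort_class = c("surgical", "ischemic",
                                             "infectious")) {
  cohort_class <- match.arg(cohort_class)
  if (length(patients) > 0) {
    stopifnot(all(vapply(patients, inherits, logical(1), "patient_record")))
    if (is.null(names(patients)) || any(names(patients) == ""))
      names(patients) <- vapply(patients, function(p) p$id, character(1))
  }
  x <- list(cohort_class = cohort_class, patients = patients)
  class(x) <- "recovery_cohort"
  x
}

#' @export
print.recovery_cohort <- function(x, ...) {
  cat("Inflammatory-recovery cohort (", x$cohort_class, "): ",
      length(x$patients), " patients\n", sep = "")
  if (length(x$patients) > 0) {
    cat(sprintf("  mean LOS %.1f d, 30-day mortality %.1f%%\n",
                mean_los(x), 100 * mean(vapply(x$patients,
                                               function(p) p$death30,
                                               logical(1)))))
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a \code{recovery_cohort}.
#' @return integer.
#' @export
n_patients <- function(cohort) length(cohort$patients)

#' Mean length of stay of a cohort
#' @param cohort a \code{recovery_cohort}.
#' @return days.
#' @export
mean_los <- function(cohort) {
  mean(vapply(cohort$patients, function(p) p$los, numeric(1)))
}

#' Long length-of-stay threshold for a cohort
#'
#' Cohorts with short typical stays (mean LOS < 7 days) use a long-stay
#' threshold of >10 days; all others use >14 days.
#'
#' @param cohort a \code{recovery_cohort}.
#' @return days (10 or 14).
#' @export
los_threshold <- function(cohort) {
  if (mean_los(cohort) < 7) 10 else 14
}

#' Write a cohort to long-format CSV files
#'
#' @param cohort a \code{recovery_cohort}.
#' @param series_path output path for the long-format series CSV with
#'   header \code{patient_id,analyte,time_days,value,units}.
#' @param patients_path output path for the patient-metadata CSV
#'   (\code{patient_id,age,gender,event_date,los,death30}).
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, series_path, patients_path) {
  stopifnot(inherits(cohort, "recovery_cohort"))
  ser <- do.call(rbind, lapply(cohort$patients, function(p) {
    do.call(rbind, lapply(names(p$series), function(an) {
      s <- p$series[[an]]
      if (nrow(s) == 0) return(NULL)
      data.frame(patient_id = p$id, analyte = an, time_days = s$time,
                 value = s$value, units = analyte_units(an))
    }))
  }))
  rownames(ser) <- NULL
  utils::write.csv(ser, series_path, row.names = FALSE)
  meta <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$id, age = p$age, gender = p$gender,
               event_date = p$event_date, los = p$los, death30 = p$death30)
  }))
  rownames(meta) <- NULL
  utils::write.csv(meta, patients_path, row.names = FALSE)
  invisible(c(series_path, patients_path))
}

#' Read a cohort from long-format CSV files
#'
#' Expects a series CSV with header
#' \code{patient_id,analyte,time_days,value,units} and a companion patient
#' table (\code{patient_id,age,gender,event_date,los,death30}). Rows with
#' non-finite values are dropped (count reported via message); duplicate
#' (patient, analyte, timestamp) rows are resolved by keeping the first.
#' Unknown analyte codes are retained.
#'
#' @param series_path path to the long-format series CSV.
#' @param patients_path path to the patient-metadata CSV.
#' @param cohort_class cohort class tag.
#' @return a \code{recovery_cohort}.
#' @export
read_cohort <- function(series_path, patients_path,
                        cohort_class = c("surgical", "ischemic",
                                         "infectious")) {
  cohort_class <- match.arg(cohort_class)
  ser <- utils::read.csv(series_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "analyte", "time_days", "value")
  missing_cols <- setdiff(need, names(ser))
  if (length(missing_cols) > 0)
    stop("series file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- !is.finite(ser$time_days) | !is.finite(ser$value)
  if (any(bad)) {
    message("read_cohort: dropped ", sum(bad), " rows with non-finite values")
    ser <- ser[!bad, , drop = FALSE]
  }
  meta <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(meta))
    stop("patient file is missing required column: patient_id")

  patients <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    rows <- ser[ser$patient_id == m$patient_id, , drop = FALSE]
    series <- split(rows, rows$analyte)
    series <- lapply(series, function(s)
      data.frame(time = s$time_days, value = s$value))
    patient_record(id = m$patient_id,
                   age = if ("age" %in% names(m)) m$age else NA_real_,
                   gender = if ("gender" %in% names(m)) m$gender else NA,
                   event_date = if ("event_date" %in% names(m)) m$event_date
                                else i,
                   los = if ("los" %in% names(m)) m$los else NA_real_,
                   death30 = isTRUE(m$death30) || identical(m$death30, "TRUE"),
                   series = series)
  })
  names(patients) <- meta$patient_id
  recovery_cohort(patients, cohort_class)
}

#' Resample a laboratory series onto a 12-hour grid
#'
#' Linear interpolation between observed points onto the 0.5-day grid
#' (gridpoints are multiples of 12 h on the event-relative time axis, so
#' repeated resampling is idempotent). No extrapolation: the grid is
#' truncated to the observed span (and to \code{[start, end]} when given).
#'
#' @param series data.frame with \code{time} (days) and \code{value}.
#' @param start,end optional window bounds in days.
#' @return data.frame (\code{time}, \code{value}) on the 12-h grid; a
#'   single-point series is returned unchanged.
#' @export
#' @examples
#' resample_12h(data.frame(time = c(0, 1), value = c(10, 20)))
resample_12h <- function(series, start = NULL, end = NULL) {
  series <- clean_series(series)
  if (nrow(series) == 0) stop("empty series")
  lo <- max(series$time[1], if (is.null(start)) -Inf else start)
  hi <- min(series$time[nrow(series)], if (is.null(end)) Inf else end)
  if (nrow(series) == 1 || lo >= hi) {
    return(data.frame(time = series$time[1], value = series$value[1]))
  }
  grid <- seq(ceiling(lo / 0.5) * 0.5, floor(hi / 0.5) * 0.5, by = 0.5)
  if (length(grid) == 0) {
    # span shorter than one grid step: fall back to the earliest point
    return(series[1, , drop = FALSE])
  }
  out <- stats::approx(series$time, series$value, xout = grid,
                       method = "linear", rule = 1)
  data.frame(time = out$x, value = out$y)
}

#' Pre-event baseline mean for an analyte
#'
#' Mean of all pre-event (t < 0) values; when no pre-event draw exists the
#' first post-event value is used as the fallback baseline.
#'
#' @param patient a \code{patient_record}.
#' @param analyte analyte code, e.g. \code{"WBC"}.
#' @return the baseline value in the analyte's units.
#' @export
baseline_mean <- function(patient, analyte) {
  s <- patient$series[[analyte]]
  if (is.null(s) || nrow(s) == 0) stop("patient ", patient$id,
                                       " has no ", analyte, " series")
  pre <- s$value[s$time < 0]
  if (length(pre) > 0) mean(pre) else s$value[1]
}

#' Apply cohort exclusion criteria
#'
#' Removes patients under 18 years old, with a hospital stay shorter than
#' 2 days, or with fewer than 2 WBC measurements. Rule-wise removal counts
#' are attached as the \code{"exclusion_counts"} attribute (a patient
#' violating several rules is counted under each).
#'
#' @param cohort a \code{recovery_cohort}.
#' @return the filtered \code{recovery_cohort}.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "recovery_cohort"))
  age <- vapply(cohort$patients, function(p) p$age, numeric(1))
  los <- vapply(cohort$patients, function(p) p$los, numeric(1))
  ncbc <- vapply(cohort$patients, function(p) {
    s <- p$series[["WBC"]]
    if (is.null(s)) 0L else nrow(s)
  }, integer(1))
  rule_age <- !is.na(age) & age < 18
  rule_los <- !is.na(los) & los < 2
  rule_cbc <- ncbc < 2L
  keep <- !(rule_age | rule_los | rule_cbc)
  out <- recovery_cohort(cohort$patients[keep], cohort$cohort_class)
  attr(out, "exclusion_counts") <- c(age_under_18 = sum(rule_age),
                                     los_under_2d = sum(rule_los),
                                     fewer_than_2_cbc = sum(rule_cbc))
  out
}

#' Locate the peak WBC used for trajectory alignment
#'
#' The search window depends on the cohort class: the 3 days after the
#' event for surgical and ischemic cohorts; the entire stay for infectious
#' cohorts in modeling mode, or the first 72 h after admission in risk
#' mode. Ties are broken by the earliest time.
#'
#' @param patient a \code{patient_record}.
#' @param cohort_class cohort class tag.
#' @param mode \code{"modeling"} or \code{"risk"}.
#' @return time of maximum WBC in the window (days).
#' @export
find_peak_wbc <- function(patient,
                          cohort_class = c("surgical", "ischemic",
                                           "infectious"),
                          mode = c("modeling", "risk")) {
  cohort_class <- match.arg(cohort_class)
  mode <- match.arg(mode)
  s <- patient$series[["WBC"]]
  if (is.null(s) || nrow(s) == 0) stop("no WBC data for patient ", patient$id)
  window_end <- if (cohort_class == "infectious" && mode == "modeling")
    Inf else 3
  w <- s[s$time >= 0 & s$time <= window_end, , drop = FALSE]
  if (nrow(w) == 0) stop("no WBC data in alignment window for patient ",
                         patient$id)
  w$time[which.max(w$value)]
}

#' Restrict a cohort to patients eligible for kinetic modeling
#'
#' Keeps patients whose peak WBC is at least 2 units (10^3/uL) above
#' their first observed WBC and whose last observation is at least 5 days
#' after the peak. Removal counts are attached as the
#' \code{"modeling_exclusions"} attribute.
#'
#' @param cohort a \code{recovery_cohort}.
#' @return the filtered \code{recovery_cohort}.
#' @export
modeling_subset <- function(cohort) {
  stopifnot(inherits(cohort, "recovery_cohort"))
  ok <- logical(length(cohort$patients))
  small_rise <- 0L
  short_follow <- 0L
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    s <- p$series[["WBC"]]
    if (is.null(s) || nrow(s) == 0) next
    tp <- tryCatch(find_peak_wbc(p, cohort$cohort_class, "modeling"),
                   error = function(e) NA_real_)
    if (is.na(tp)) next
    wbc_max <- s$value[match(tp, s$time)]
    rise_ok <- (wbc_max - s$value[1]) >= 2
    follow_ok <- (max(s$time) - tp) >= 5
    if (!rise_ok) small_rise <- small_rise + 1L
    if (!follow_ok) short_follow <- short_follow + 1L
    ok[i] <- rise_ok && follow_ok
  }
  out <- recovery_cohort(cohort$patients[ok], cohort$cohort_class)
  attr(out, "modeling_exclusions") <- c(rise_below_2 = small_rise,
                                        under_5d_postpeak = short_follow)
  out
}
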