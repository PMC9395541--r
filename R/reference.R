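#' Mask of patients with favorable outcomes
#'
#' A favorable recovery means the patient survived past 30 days and had a
#' length of stay below the cohort's long-stay threshold (10 days for
#' cohorts with mean LOS < 7 days, 14 days otherwise; see
#' \code{\link{los_threshold}}).
#'
#' @param cohort a \code{recovery_cohort}.
#' @return named logical vector over patients.
#' @export
good_outcome_mask <- function(cohort) {
  thr <- los_threshold(cohort)
  vapply(cohort$patients,
         function(p) !p$death30 && p$los < thr,
         logical(1))
}

#' Adverse-outcome indicator for each patient
#'
#' Adverse = death within 30 days or length of stay above the cohort
#' threshold. (Strictly at or above the threshold counts as non-favorable
#' under \code{\link{good_outcome_mask}}; the adverse label uses strictly
#' greater, matching a "long stay" reading. The two agree except exactly
#' at the threshold.)
#'
#' @param cohort a \code{recovery_cohort}.
#' @return named logical vector over patients.
#' @export
adverse_outcome <- function(cohort) {
  thr <- los_threshold(cohort)
  vapply(cohort$patients,
         function(p) p$death30 || p$los > thr,
         logical(1))
}

# normalized, 12-h resampled WBC and PLT series for one patient on the
# chosen alignment origin; returns NULL when either series is unusable
normalized_pair <- function(patient, cohort_class, alignment, mode = "risk") {
  sw <- patient$series[["WBC"]]
  sp <- patient$series[["PLT"]]
  if (is.null(sw) || is.null(sp) || nrow(sw) < 2 || nrow(sp) < 2) return(NULL)
  origin <- 0
  if (alignment == "peak_wbc" ||
      (alignment == "event_time" && cohort_class == "infectious")) {
    origin <- tryCatch(find_peak_wbc(patient, cohort_class, mode),
                       error = function(e) NA_real_)
    if (is.na(origin)) return(NULL)
  }
  bw <- baseline_mean(patient, "WBC")
  bp <- baseline_mean(patient, "PLT")
  if (bw <= 0 || bp <= 0) return(NULL)
  w <- data.frame(time = sw$time - origin, value = sw$value / bw)
  p <- data.frame(time = sp$time - origin, value = sp$value / bp)
  list(wbc = resample_12h(w, start = 0),
       plt = resample_12h(p, start = 0))
}

#' Mean normalized WBC-PLT trajectory of selected patients
#'
#' Each selected patient's WBC and PLT series are normalized by their
#' pre-event baseline means, resampled onto the common 12-h grid (aligned
#' to the event, or to the peak WBC), and averaged pointwise over the
#' patients contributing data at each gridpoint (available-case
#' averaging; patients discharged before a gridpoint simply drop out).
#' Gridpoints supported by fewer than \code{min_n} patients are trimmed,
#' so late times are not dominated by a handful of long-stay patients.
#'
#' @param cohort a \code{recovery_cohort}.
#' @param mask logical vector selecting patients (default: favorable
#'   outcomes via \code{\link{good_outcome_mask}}).
#' @param alignment \code{"event_time"} (default; infectious cohorts then
#'   align on the peak WBC within the first 72 h) or \code{"peak_wbc"}.
#' @param min_n minimum patients per retained gridpoint.
#' @return object of class \code{reference_trajectory}: list with
#'   \code{grid} (days), \code{mean_wbc_norm}, \code{mean_plt_norm},
#'   \code{n_contributing}, the alignment used, and (after
#'   \code{\link{direction_bands}}) directional percentile bands.
#' @export
mean_trajectory <- function(cohort, mask = NULL,
                            alignment = c("event_time", "peak_wbc"),
                            min_n = 10) {
  alignment <- match.arg(alignment)
  if (is.null(mask)) mask <- good_outcomes_default(cohort)
  stopifnot(length(mask) == n_patients(cohort))
  sel <- cohort$patients[mask]
  if (length(sel) == 0) stop("no patients selected for the reference")

  pairs <- lapply(sel, normalized_pair, cohort_class = cohort$cohort_class,
                  alignment = alignment)
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  if (length(pairs) == 0) stop("no selected patient has usable WBC and PLT")

  gmax <- max(vapply(pairs, function(z)
    max(z$wbc$time[nrow(z$wbc)], z$plt$time[nrow(z$plt)]), numeric(1)))
  grid <- seq(0, gmax, by = 0.5)
  sum_w <- sum_p <- n_w <- numeric(length(grid))
  for (z in pairs) {
    iw <- match(round(z$wbc$time * 2), round(grid * 2))
    ip <- match(round(z$plt$time * 2), round(grid * 2))
    both <- intersect(iw[!is.na(iw)], ip[!is.na(ip)])
    wv <- z$wbc$value[match(grid[both], z$wbc$time)]
    pv <- z$plt$value[match(grid[both], z$plt$time)]
    sum_w[both] <- sum_w[both] + wv
    sum_p[both] <- sum_p[both] + pv
    n_w[both] <- n_w[both] + 1
  }
  keep <- n_w >= max(min_n, 1)
  if (!any(keep)) stop("no gridpoint reaches the minimum patient count")
  out <- list(grid = grid[keep],
              mean_wbc_norm = sum_w[keep] / n_w[keep],
              mean_plt_norm = sum_p[keep] / n_w[keep],
              n_contributing = as.integer(n_w[keep]),
              alignment = alignment,
              cohort_class = cohort$cohort_class,
              bands = NULL)
  class(out) <- "reference_trajectory"
  out
}

# default reference population: favorable outcomes
good_outcomes_default <- function(cohort) good_outcome_mask(cohort)

#' @export
print.reference_trajectory <- function(x, ...) {
  cat("Reference WBC-PLT trajectory (", x$cohort_class, ", aligned on ",
      x$alignment, ")\n", sep = "")
  cat(sprintf("  %d gridpoints over %.1f-%.1f d, %d-%d contributing patients\n",
              length(x$grid), min(x$grid), max(x$grid),
              min(x$n_contributing), max(x$n_contributing)))
  if (!is.null(x$bands))
    cat("  directional bands at percentiles:",
        paste(unique(x$bands$percentile), collapse = ", "), "\n")
  invisible(x)
}

# value of the reference at a grid time (NA outside the retained grid)
reference_at <- function(reference, t) {
  i <- match(round(t * 2), round(reference$grid * 2))
  c(wbc = if (is.na(i)) NA_real_ else reference$mean_wbc_norm[i],
    plt = if (is.na(i)) NA_real_ else reference$mean_plt_norm[i])
}

# reference 24-h change vector ending at day t
reference_delta <- function(reference, t) {
  now <- reference_at(reference, t)
  prev <- reference_at(reference, t - 1)
  c(dw = now[["wbc"]] - prev[["wbc"]], dp = now[["plt"]] - prev[["plt"]])
}

#' Directional percentile bands around the reference trajectory
#'
#' For each post-event day, computes the angle between each selected
#' patient's normalized 24-h WBC-PLT change vector and the reference
#' trajectory's change vector for that day, and summarizes the empirical
#' distribution at the requested percentiles (midpoint interpolation).
#' Patient-days with a zero change vector are excluded (their direction
#' is undefined).
#'
#' @param cohort a \code{recovery_cohort}.
#' @param mask logical patient selector (default favorable outcomes).
#' @param reference a \code{reference_trajectory}.
#' @param percentiles percent levels, default \code{c(50, 80, 90)}.
#' @param days post-event days to evaluate (default 1 to 7).
#' @return the reference with a \code{bands} data.frame
#'   (\code{day}, \code{percentile}, \code{angle}) attached; the bands
#'   are also returned as the \code{"bands"} attribute-free element.
#' @export
direction_bands <- function(cohort, mask = NULL, reference,
                            percentiles = c(50, 80, 90), days = 1:7) {
  sc <- risk_scores(cohort, reference, days = days, mask = mask)
  sc <- sc[is.finite(sc$direction), , drop = FALSE]
  if (nrow(sc) == 0) stop("no patient has two consecutive days of data")
  rows <- list()
  for (d in sort(unique(sc$day))) {
    ang <- sc$direction[sc$day == d]
    qs <- stats::quantile(ang, probs = percentiles / 100, type = 5,
                          names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(day = d, percentile = percentiles,
                                           angle = qs)
  }
  bands <- do.call(rbind, rows)
  rownames(bands) <- NULL
  reference$bands <- bands
  reference
}

#' Serialize a reference trajectory to CSV
#'
#' Writes the gridded means and contribution counts (and directional
#' bands when present) so risk scoring can run without access to the
#' exploratory cohort.
#'
#' @param reference a \code{reference_trajectory}.
#' @param path output CSV path; bands (if any) go to
#'   \code{<path base>_bands.csv}.
#' @return invisibly, the path(s) written.
#' @export
write_reference <- function(reference, path) {
  df <- data.frame(time = reference$grid,
                   mean_wbc_norm = reference$mean_wbc_norm,
                   mean_plt_norm = reference$mean_plt_norm,
                   n = reference$n_contributing)
  utils::write.csv(df, path, row.names = FALSE)
  paths <- path
  if (!is.null(reference$bands)) {
    bp <- sub("\\.csv$", "_bands.csv", path)
    utils::write.csv(reference$bands, bp, row.names = FALSE)
    paths <- c(paths, bp)
  }
  invisible(paths)
}

#' Read a reference trajectory from CSV
#'
#' @param path CSV written by \code{\link{write_reference}}.
#' @param cohort_class,alignment metadata to attach.
#' @return a \code{reference_trajectory}.
#' @export
read_reference <- function(path, cohort_class = "surgical",
                           alignment = "event_time") {
  df <- utils::read.csv(path)
  out <- list(grid = df$time, mean_wbc_norm = df$mean_wbc_norm,
              mean_plt_norm = df$mean_plt_norm,
              n_contributing = as.integer(df$n),
              alignment = alignment, cohort_class = cohort_class,
              bands = NULL)
  bp <- sub("\\.csv$", "_bands.csv", path)
  if (file.exists(bp)) out$bands <- utils::read.csv(bp)
  class(out) <- "reference_trajectory"
  out
}

#' Phase-plane plot of a reference trajectory
#'
#' @param x a \code{reference_trajectory}.
#' @param ... passed to \code{plot}.
#' @export
plot.reference_trajectory <- function(x, ...) {
  graphics::plot(x$mean_wbc_norm, x$mean_plt_norm, type = "o", pch = 16,
                 cex = 0.6, xlab = "WBC / baseline", ylab = "PLT / baseline",
                 main = "Mean WBC-PLT recovery trajectory", ...)
  graphics::points(x$mean_wbc_norm[1], x$mean_plt_norm[1], col = "red",
                   pch = 17)
  invisible(x)
}
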