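#' Build the patient-by-(marker x time) feature matrix
#'
#' Each marker series is normalized by the patient's pre-event baseline
#' mean, linearly interpolated, and sampled every 12 h from the event
#' until discharge; values after discharge are set exactly to 0 (so stays
#' of different lengths live in one rectangular matrix), and values at
#' in-stay gridpoints outside the observed span take the nearest
#' observation. Patients with fewer than \code{min_sets} distinct
#' measurement times are held out of cluster definition (reported via the
#' \code{"held_out"} attribute) but still receive rows.
#'
#' @param cohort a \code{recovery_cohort}.
#' @param markers analyte codes to include.
#' @param horizon grid end in days (default: latest discharge, capped at
#'   21 days).
#' @param min_sets minimum distinct measurement times for a patient to
#'   help define clusters.
#' @return numeric matrix (patients x features) with attributes
#'   \code{"marker"} and \code{"time"} (column metadata) and
#'   \code{"held_out"} (logical by patient).
#' @export
build_feature_matrix <- function(cohort, markers = NULL, horizon = NULL,
                                 min_sets = 3L) {
  stopifnot(inherits(cohort, "recovery_cohort"))
  if (is.null(markers)) {
    markers <- Reduce(union, lapply(cohort$patients,
                                    function(p) names(p$series)))
  }
  if (is.null(horizon)) {
    horizon <- min(max(vapply(cohort$patients, function(p) p$los,
                              numeric(1))), 21)
  }
  grid <- seq(0, horizon, by = 0.5)
  n <- n_patients(cohort)
  mat <- matrix(0, nrow = n, ncol = length(markers) * length(grid),
                dimnames = list(names(cohort$patients), NULL))
  col_marker <- rep(markers, each = length(grid))
  col_time <- rep(grid, times = length(markers))
  held_out <- logical(n)

  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    all_times <- unique(unlist(lapply(p$series,
                                      function(s) s$time[s$time >= 0])))
    held_out[i] <- length(all_times) < min_sets
    in_stay <- grid <= p$los
    for (j in seq_along(markers)) {
      s <- p$series[[markers[j]]]
      if (is.null(s) || nrow(s) == 0) next
      base <- baseline_mean(p, markers[j])
      if (!is.finite(base) || base == 0) next
      cols <- (j - 1) * length(grid) + which(in_stay)
      if (nrow(s) == 1) {
        vals <- rep(s$value / base, sum(in_stay))
      } else {
        vals <- stats::approx(s$time, s$value / base,
                              xout = grid[in_stay], rule = 2)$y
      }
      mat[i, cols] <- vals
    }
  }
  structure(mat, marker = col_marker, time = col_time, held_out = held_out)
}

#' Size-constrained k-means clustering of trajectory features
#'
#' Runs k-means for k = 2, 3, ... and keeps the largest k for which every
#' cluster exceeds \code{min_cluster_size} members. Patients held out of
#' cluster definition (too few measurement sets) are assigned to their
#' nearest centroid afterwards. Seed the session for reproducible labels.
#'
#' @param mat feature matrix from \code{\link{build_feature_matrix}} (or
#'   any numeric matrix; rows = patients).
#' @param min_cluster_size minimum cluster membership (default 50).
#' @param k_max largest k to try (default bounded by
#'   \code{nrow / min_cluster_size}).
#' @param nstart random restarts per k.
#' @return list with \code{k}, \code{labels} (all rows, held-out included),
#'   \code{centers}, \code{objective} (total within-cluster sum of
#'   squares) and \code{held_out}. When no k >= 2 satisfies the size rule,
#'   returns k = 1 with a warning.
#' @export
choose_k_and_cluster <- function(mat, min_cluster_size = 50, k_max = NULL,
                                 nstart = 10) {
  held_out <- attr(mat, "held_out")
  if (is.null(held_out)) held_out <- rep(FALSE, nrow(mat))
  core <- mat[!held_out, , drop = FALSE]
  if (nrow(core) < min_cluster_size)
    stop("fewer defining patients than the minimum cluster size")
  if (is.null(k_max)) k_max <- max(2L, nrow(core) %/% min_cluster_size)

  best <- NULL
  for (k in 2:k_max) {
    km <- stats::kmeans(core, centers = k, nstart = nstart, iter.max = 100)
    if (all(km$size > min_cluster_size)) best <- km
  }
  if (is.null(best)) {
    warning("no k >= 2 keeps all clusters above the size threshold; ",
            "returning a single cluster")
    centers <- matrix(colMeans(core), nrow = 1)
    labels <- rep(1L, nrow(mat))
    return(list(k = 1L, labels = stats::setNames(labels, rownames(mat)),
                centers = centers,
                objective = sum(scale(core, scale = FALSE)^2),
                held_out = held_out))
  }
  labels <- integer(nrow(mat))
  labels[!held_out] <- best$cluster
  if (any(held_out)) {
    ho <- which(held_out)
    for (i in ho) {
      d2 <- colSums((t(best$centers) - mat[i, ])^2)
      labels[i] <- which.min(d2)
    }
  }
  list(k = nrow(best$centers),
       labels = stats::setNames(labels, rownames(mat)),
       centers = best$centers, objective = best$tot.withinss,
       held_out = held_out)
}

#' Filter markers by cross-cluster variation and mutual correlation
#'
#' Two rules, applied after a provisional size-constrained clustering:
#' (1) markers whose cluster means vary by less than 10% (max pairwise
#' relative difference of the per-cluster mean normalized values) carry
#' no trajectory signal and are dropped; (2) groups of markers with
#' pairwise Pearson correlation above 0.9 across patient-time values are
#' collapsed to a single representative (preferring \code{keep}, default
#' HCT, for the red-cell group; otherwise the first member).
#'
#' @param cohort a \code{recovery_cohort}.
#' @param markers candidate analyte codes (at least 2).
#' @param min_cluster_size provisional clustering size rule.
#' @param variation_threshold relative-variation cutoff (default 0.1).
#' @param cor_threshold correlation-collapse cutoff (default 0.9).
#' @param keep preferred representatives for collapsed groups.
#' @param horizon passed to \code{\link{build_feature_matrix}}.
#' @return character vector of retained markers.
#' @export
filter_markers <- function(cohort, markers, min_cluster_size = 50,
                           variation_threshold = 0.1, cor_threshold = 0.9,
                           keep = "HCT", horizon = NULL) {
  stopifnot(length(markers) >= 2)
  mat <- build_feature_matrix(cohort, markers, horizon = horizon)
  cl <- choose_k_and_cluster(mat, min_cluster_size = min_cluster_size)
  labels <- cl$labels
  col_marker <- attr(mat, "marker")

  retained <- character(0)
  for (mk in markers) {
    cols <- col_marker == mk
    cluster_means <- vapply(seq_len(cl$k), function(g)
      mean(mat[labels == g, cols, drop = FALSE]), numeric(1))
    center <- mean(abs(cluster_means))
    variation <- if (center == 0) 0 else
      (max(cluster_means) - min(cluster_means)) / center
    if (cl$k == 1L) variation <- 0
    if (variation >= variation_threshold) retained <- c(retained, mk)
  }
  if (length(retained) == 0) stop("all markers filtered out by the ",
                                  "variation rule")
  if (length(retained) == 1) return(retained)

  # collapse highly correlated groups (connected components of the
  # r > threshold graph), keeping the configured representative
  vecs <- sapply(retained, function(mk)
    as.numeric(mat[, col_marker == mk, drop = FALSE]))
  cm <- stats::cor(vecs)
  m <- length(retained)
  comp <- seq_len(m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (!is.na(cm[i, j]) && cm[i, j] > cor_threshold) {
      comp[comp == comp[j]] <- comp[i]
    }
  }
  final <- character(0)
  for (g in unique(comp)) {
    members <- retained[comp == g]
    rep_mk <- intersect(keep, members)
    final <- c(final, if (length(rep_mk) > 0) rep_mk[1] else members[1])
  }
  final[order(match(final, markers))]
}

#' Permutation-null significance of a trajectory clustering
#'
#' Tests whether the clustering objective (total within-cluster sum of
#' squares) is better than expected for data with the same column
#' marginals but no joint trajectory structure. Each null draw shuffles
#' every column independently across patients, reruns k-means at the same
#' k, and records the objective; the p-value is the add-one-corrected
#' fraction of null objectives at least as good (as small) as observed.
#' This column-shuffle null is a simplification of cluster-significance
#' testing against synthetic data and is labeled as such in outputs.
#'
#' @param mat numeric feature matrix (rows = patients).
#' @param clustering result of \code{\link{choose_k_and_cluster}}.
#' @param n_null number of null draws (at least 20).
#' @param nstart k-means restarts per null draw.
#' @return list with \code{p}, \code{observed}, \code{null} (objectives)
#'   and \code{method = "column-shuffle permutation null"}.
#' @export
cluster_significance <- function(mat, clustering, n_null = 200, nstart = 5) {
  if (n_null < 20) stop("n_null must be at least 20")
  k <- clustering$k
  if (k < 2) stop("significance requires at least 2 clusters")
  held_out <- clustering$held_out
  if (is.null(held_out)) held_out <- rep(FALSE, nrow(mat))
  core <- mat[!held_out, , drop = FALSE]
  obs <- clustering$objective
  null_obj <- numeric(n_null)
  n <- nrow(core)
  for (b in seq_len(n_null)) {
    perm <- apply(core, 2, function(col) col[sample.int(n)])
    km <- stats::kmeans(perm, centers = k, nstart = nstart, iter.max = 50)
    null_obj[b] <- km$tot.withinss
  }
  p <- (1 + sum(null_obj <= obs)) / (n_null + 1)
  list(p = p, observed = obs, null = null_obj,
       method = "column-shuffle permutation null")
}
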