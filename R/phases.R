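#' Define phase windows for one lineage
#'
#' A phase window is a contiguous time interval of a differentiation course.
#' Windows of one lineage are disjoint, ordered and jointly cover every
#' sampling time: a time t belongs to window i when `start_hours[i] <= t <
#' start_hours[i+1]` (the last window is closed at its `end_hours`).
#'
#' @param lineage Lineage label.
#' @param label Character vector of window labels, e.g. `"6-24h"`.
#' @param start_hours,end_hours Numeric window bounds; starts strictly
#'   increasing, `start <= end`, and window i+1 starts where window i ends.
#' @return A `phase_windows` data.frame.
#' @export
phase_windows <- function(lineage, label, start_hours, end_hours) {
  stopifnot(length(label) == length(start_hours),
            length(label) == length(end_hours))
  if (any(diff(start_hours) <= 0)) {
    stop("window starts must be strictly increasing", call. = FALSE)
  }
  if (any(start_hours > end_hours)) {
    stop("window start must not exceed end", call. = FALSE)
  }
  out <- data.frame(lineage = lineage, label = label,
                    start_hours = start_hours, end_hours = end_hours,
                    stringsAsFactors = FALSE)
  class(out) <- c("phase_windows", "data.frame")
  out
}

#' Default osteoblast phase windows
#'
#' The five phases of the osteoblast course: immediate early (1 h), 6-24 h,
#' 30-48 h, 4-6 d and 8-14 d, as window intervals over the 15-point sampling
#' grid.
#'
#' @return A [phase_windows()] data.frame with five rows.
#' @export
osteoblast_phase_windows <- function() {
  phase_windows("osteoblast",
                label = c("1h", "6-24h", "30-48h", "4-6d", "8-14d"),
                start_hours = c(0.5, 3, 27, 60, 168),
                end_hours = c(3, 27, 60, 168, 336))
}

#' Default adipocyte phase windows
#'
#' The four phases of the adipocyte course, labeled 2d, 4d, 8d and 10-14d.
#' Boundaries beyond the named cluster labels are a documented convention (see
#' the methods vignette); the first window opens at 1 h so that the earliest
#' sampling time is covered.
#'
#' @return A [phase_windows()] data.frame with four rows.
#' @export
adipocyte_phase_windows <- function() {
  phase_windows("adipocyte",
                label = c("2d", "4d", "8d", "10-14d"),
                start_hours = c(1, 60, 120, 216),
                end_hours = c(60, 120, 216, 336))
}

window_index <- function(time, windows) {
  if (time < windows$start_hours[1] ||
      time > windows$end_hours[nrow(windows)]) {
    return(NA_integer_)
  }
  findInterval(time, windows$start_hours)
}

#' Standardize an expression profile
#'
#' Z-scores a ratio series across its time points (zero mean, unit variance;
#' population standard deviation, so a two-point series maps to -1, 1). A
#' constant series maps to all zeros with a message, so that
#' correlation-based displays degrade gracefully.
#'
#' @param values Numeric vector of log2 ratios (length >= 2).
#' @return Standardized numeric vector.
#' @export
standardize_profile <- function(values) {
  stopifnot(length(values) >= 2L)
  s <- sqrt(mean((values - mean(values))^2))
  if (s == 0) {
    message("constant profile standardized to all zeros")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Hierarchically cluster gene profiles for heat-map ordering
#'
#' Deterministic agglomerative clustering of gene ratio profiles, returning
#' the left-to-right leaf order used to arrange heat-map rows and the merge
#' tree.
#'
#' @param ratios A `tf_ratios` (genes x times), or a plain numeric matrix with
#'   rownames.
#' @param distance `"correlation"` (1 - Pearson correlation across time
#'   points) or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return A `gene_clustering` list: `gene_order` (character permutation of
#'   gene ids), `merge_tree` (an `hclust` object), `distance_name`,
#'   `linkage_name`.
#' @export
cluster_genes <- function(ratios, distance = c("correlation", "euclidean"),
                          linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  values <- if (inherits(ratios, "tf_ratios")) ratios$values else ratios
  stopifnot(is.matrix(values), nrow(values) >= 2L)
  if (any(!is.finite(values))) {
    stop("non-finite values in profiles", call. = FALSE)
  }
  d <- if (distance == "correlation") {
    cc <- suppressWarnings(stats::cor(t(values)))
    if (any(!is.finite(cc))) {
      stop("correlation distance undefined (constant profile present)",
           call. = FALSE)
    }
    stats::as.dist(1 - cc)
  } else {
    stats::dist(values, method = "euclidean")
  }
  tree <- stats::hclust(d, method = linkage)
  structure(list(gene_order = rownames(values)[tree$order],
                 merge_tree = tree,
                 distance_name = distance,
                 linkage_name = linkage),
            class = "gene_clustering")
}

#' Assign regulated genes to temporal phases
#'
#' Each gene whose behavior call fired gets one assignment per fired
#' direction: the UP direction peaks at the maximum ratio over the time points
#' where the up criterion fired (earliest time on ties), the DOWN direction at
#' the minimum over down-fired points; the peak time selects the containing
#' phase window. Raw (unstandardized) ratios are read, so the assignment is
#' invariant to profile standardization.
#'
#' @param calls A `tf_calls` for the lineage.
#' @param ratios The matching `tf_ratios`.
#' @param windows A [phase_windows()] covering the lineage's sampling times.
#' @return A `phase_assignments` data.frame: `gene_id`, `lineage`, `direction`
#'   (UP/DOWN), `window_label`, `peak_time_hours`, `peak_value`.
#' @export
assign_phases <- function(calls, ratios, windows) {
  stopifnot(inherits(windows, "phase_windows"),
            identical(unique(windows$lineage), ratios$lineage))
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    gene <- calls$gene_id[i]
    for (direction in c("UP", "DOWN")) {
      fired <- if (direction == "UP") calls$up_times[[i]] else calls$down_times[[i]]
      if (length(fired) == 0L) next
      idx <- match(fired, ratios$times)
      vals <- ratios$values[gene, idx]
      best <- if (direction == "UP") which(vals == max(vals)) else
                                     which(vals == min(vals))
      best <- best[1L]  # earliest time wins ties (times are ordered)
      peak_time <- fired[best]
      w <- window_index(peak_time, windows)
      if (is.na(w)) {
        stop("peak time ", peak_time, " h of gene ", gene,
             " lies outside all phase windows", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene, lineage = ratios$lineage, direction = direction,
        window_label = windows$label[w], peak_time_hours = peak_time,
        peak_value = unname(vals[best]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(gene_id = character(0), lineage = character(0),
               direction = character(0), window_label = character(0),
               peak_time_hours = numeric(0), peak_value = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("phase_assignments", "data.frame")
  out
}

#' Detect phase windows from sample-axis structure
#'
#' Auxiliary, data-driven route to phase boundaries: clusters the lineage's
#' sample columns by correlation distance (average linkage), chooses the
#' number of phases by the largest gap in merge heights (capped at
#' `max_phases`; all-equal heights give a single phase), enforces contiguity
#' in time by closing each cluster over the span of its occurrences, and
#' converts the resulting contiguous sample groups into windows whose
#' boundaries lie midway between adjacent samples of different groups.
#'
#' @param ratios A `tf_ratios` for one lineage.
#' @param max_phases Maximum number of windows to return.
#' @return A [phase_windows()] partitioning the lineage's sampling times.
#' @export
detect_phase_windows <- function(ratios, max_phases = 6L) {
  values <- ratios$values
  times <- ratios$times
  n <- ncol(values)
  stopifnot(n >= 2L, max_phases >= 1L)
  cc <- suppressWarnings(stats::cor(values))
  if (any(!is.finite(cc))) {
    stop("correlation distance undefined between sample columns", call. = FALSE)
  }
  tree <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  heights <- sort(tree$height, decreasing = TRUE)  # length n-1
  kmax <- min(max_phases, n)
  k <- 1L
  if (kmax >= 2L) {
    # cutting into k clusters removes the k-1 highest merges; gap(k) is the
    # height drop across that cut
    gaps <- vapply(2:kmax, function(kk) {
      upper <- heights[kk - 1L]
      lower <- if (kk <= length(heights)) heights[kk] else 0
      upper - lower
    }, numeric(1))
    if (max(gaps) > 1e-8) k <- (2:kmax)[which.max(gaps)]
  }
  labels <- stats::cutree(tree, k = k)[order(times)]
  ord_times <- sort(times)
  groups <- contiguous_groups(labels)
  boundaries <- which(diff(groups) != 0)
  starts <- c(ord_times[1] / 2,
              (ord_times[boundaries] + ord_times[boundaries + 1]) / 2)
  ends <- c(starts[-1], ord_times[n])
  phase_windows(ratios$lineage,
                label = vapply(seq_along(starts), function(i) {
                  in_w <- ord_times >= starts[i] & ord_times <= ends[i]
                  format_window_label(range(ord_times[in_w]))
                }, ""),
                start_hours = starts, end_hours = ends)
}

# Close every cluster label over the span of its occurrences, so a label
# recurring at non-adjacent times absorbs everything in between; iterate to a
# fixed point and renumber groups 1..k in time order.
contiguous_groups <- function(labels) {
  repeat {
    changed <- FALSE
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      if (length(idx) == 0L) next
      span <- range(idx)
      inside <- seq(span[1], span[2])
      if (!all(labels[inside] == lab)) {
        labels[inside] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cumsum(c(1L, diff(labels) != 0))
}

format_window_label <- function(rng) {
  fmt <- function(t) {
    if (t >= 48 && t %% 24 == 0) paste0(t / 24, "d") else paste0(t, "h")
  }
  if (rng[1] == rng[2]) fmt(rng[1]) else paste0(fmt(rng[1]), "-", fmt(rng[2]))
}

#' Per-window membership report
#'
#' Summarizes phase assignments into one row per (window, direction) with the
#' member count and the member gene ids ordered by peak time then gene id
#' (chronological cluster order). Windows or directions with no members get a
#' zero row.
#'
#' @param assignments A `phase_assignments` from [assign_phases()].
#' @param windows The [phase_windows()] the assignments were made against.
#' @param directions Directions to report; default both `"UP"` and `"DOWN"`.
#' @return A `phase_report` data.frame: `lineage`, `window_label`,
#'   `direction`, `n`, `members` (list column of gene-id vectors).
#' @export
phase_report <- function(assignments, windows, directions = c("UP", "DOWN")) {
  stopifnot(inherits(windows, "phase_windows"))
  grid <- expand.grid(window_label = windows$label, direction = directions,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$window_label, windows$label),
                     match(grid$direction, directions)), , drop = FALSE]
  members <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- assignments[assignments$window_label == grid$window_label[i] &
                       assignments$direction == grid$direction[i], , drop = FALSE]
    sel <- sel[order(sel$peak_time_hours, sel$gene_id), , drop = FALSE]
    sel$gene_id
  })
  out <- data.frame(lineage = unique(windows$lineage),
                    window_label = grid$window_label,
                    direction = grid$direction,
                    n = vapply(members, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$members <- members
  rownames(out) <- NULL
  class(out) <- c("phase_report", "data.frame")
  out
}
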