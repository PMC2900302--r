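BEHAVIOR_LEVELS <- c("UP", "DOWN", "UP_DOWN", "UNCHANGED")

#' Classification parameters for behavior calls
#'
#' @param fold_threshold Positive absolute log2-ratio cutoff; a gene fires at a
#'   time point when its ratio is strictly greater than `fold_threshold` (up)
#'   or strictly less than `-fold_threshold` (down). Default 1 (two-fold).
#' @param sd_multiplier Positive multiplier `k` of the per-time-point
#'   array-wide standard deviation; ratios beyond mean +/- k*SD also fire.
#'   Default 3.
#' @return A `classification_params` list.
#' @export
classification_params <- function(fold_threshold = 1, sd_multiplier = 3) {
  stopifnot(is.numeric(fold_threshold), fold_threshold > 0,
            is.numeric(sd_multiplier), sd_multiplier > 0)
  structure(list(fold_threshold = fold_threshold,
                 sd_multiplier = sd_multiplier),
            class = "classification_params")
}

#' Compute log2 ratios versus the time-0 control
#'
#' For one lineage, subtracts the shared uninduced control sample's log2
#' intensity from each time point's log2 intensity, gene-wise. Input
#' intensities must already be on the log2 scale; linear-scale input is the
#' caller's responsibility to transform (no auto-detection).
#'
#' @param dataset A `tf_dataset` as returned by [build_reference_fixture()],
#'   [generate_dataset()] or [read_dataset()]: a list with `expr` (numeric
#'   matrix, genes x samples, log2 intensities, rownames = gene ids) and
#'   `meta` (data.frame with `sample_id`, `lineage`, `time_hours`,
#'   `is_control`).
#' @param lineage Lineage label, e.g. `"osteoblast"` or `"adipocyte"`.
#' @return A `tf_ratios` list: `lineage`, `times` (strictly increasing hours),
#'   `values` (genes x times matrix of log2 ratios, rownames = gene ids).
#' @export
compute_ratios <- function(dataset, lineage) {
  meta <- dataset$meta
  expr <- dataset$expr
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  ctrl <- meta$sample_id[meta$is_control == 1L]
  if (length(ctrl) != 1L) {
    stop("expected exactly one control sample, found ", length(ctrl),
         call. = FALSE)
  }
  sel <- meta[meta$lineage == lineage & meta$is_control == 0L, , drop = FALSE]
  if (nrow(sel) < 1L) {
    stop("no samples for lineage: ", lineage, call. = FALSE)
  }
  if (anyDuplicated(sel$time_hours)) {
    dup <- unique(sel$time_hours[duplicated(sel$time_hours)])
    stop("duplicate sample for (", lineage, ", ",
         paste(dup, collapse = ", "), " h)", call. = FALSE)
  }
  sel <- sel[order(sel$time_hours), , drop = FALSE]
  values <- expr[, sel$sample_id, drop = FALSE] - expr[, ctrl]
  if (any(!is.finite(values))) {
    stop("non-finite log2 ratio encountered for lineage ", lineage,
         call. = FALSE)
  }
  colnames(values) <- NULL
  structure(list(lineage = lineage, times = as.numeric(sel$time_hours),
                 values = values),
            class = "tf_ratios")
}

#' Array-wide outlier bounds at one time point
#'
#' Mean +/- k standard deviations of the log2 ratios of all catalog genes at a
#' single time point (the array-adaptive arm of the classification rule). The
#' standard deviation is the population form (denominator n).
#'
#' @param values Numeric vector of log2 ratios across genes (>= 2 values).
#' @param k Non-negative standard-deviation multiplier.
#' @return Numeric vector `c(lower, upper)`.
#' @export
per_timepoint_bounds <- function(values, k) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("need at least 2 values to compute bounds", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite values in bounds input",
                                    call. = FALSE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  c(lower = m - k * s, upper = m + k * s)
}

#' Classify one gene's ratio course
#'
#' A time point fires upward when the log2 ratio strictly exceeds the fold
#' threshold or the upper array-wide bound; downward when it is strictly below
#' the negated threshold or the lower bound. The call is UP if only upward
#' points exist, DOWN if only downward, UP_DOWN if both, UNCHANGED if neither.
#'
#' @param values Numeric vector of log2 ratios, aligned to `times`.
#' @param times Sampling times in hours.
#' @param lower,upper Per-time-point bounds, same length as `values` (from
#'   [per_timepoint_bounds()] applied per time point across all genes).
#' @param params A [classification_params()].
#' @return List with `call` (one of UP, DOWN, UP_DOWN, UNCHANGED), `up_times`
#'   and `down_times` (hour values where each criterion fired).
#' @export
classify_gene <- function(values, times, lower, upper,
                          params = classification_params()) {
  n <- length(values)
  if (length(times) != n || length(lower) != n || length(upper) != n) {
    stop("series, times and bounds must have equal length", call. = FALSE)
  }
  up <- values > params$fold_threshold | values > upper
  down <- values < -params$fold_threshold | values < lower
  call <- if (any(up) && any(down)) "UP_DOWN"
          else if (any(up)) "UP"
          else if (any(down)) "DOWN"
          else "UNCHANGED"
  list(call = call, up_times = times[up], down_times = times[down])
}

#' Classify every gene of one lineage
#'
#' Computes per-time-point array-wide bounds across all genes in the ratio
#' matrix, then applies [classify_gene()] to each gene. Optionally restricts
#' the classified genes (e.g. to the transcription-factor universe) while the
#' bounds remain computed over the full matrix.
#'
#' @param ratios A `tf_ratios` from [compute_ratios()].
#' @param params A [classification_params()].
#' @param genes Optional character vector of gene ids to classify; default all.
#' @return A `tf_calls` data.frame: `gene_id`, `lineage`, `call` (factor with
#'   levels UP, DOWN, UP_DOWN, UNCHANGED), `up_times`, `down_times` (list
#'   columns of hour vectors).
#' @export
classify_lineage <- function(ratios, params = classification_params(),
                             genes = NULL) {
  values <- ratios$values
  if (nrow(values) >= 2L) {
    bounds <- apply(values, 2, per_timepoint_bounds, k = params$sd_multiplier)
    lower <- bounds["lower", ]
    upper <- bounds["upper", ]
  } else {
    # the array-adaptive criterion is undefined for a single gene; only the
    # fold-threshold arm can fire
    lower <- rep(-Inf, ncol(values))
    upper <- rep(Inf, ncol(values))
  }
  if (is.null(genes)) genes <- rownames(values)
  missing <- setdiff(genes, rownames(values))
  if (length(missing) > 0L) {
    stop("gene(s) absent from ratio matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  res <- lapply(genes, function(g) {
    classify_gene(values[g, ], ratios$times, lower, upper, params)
  })
  out <- data.frame(gene_id = genes, lineage = ratios$lineage,
                    call = factor(vapply(res, `[[`, "", "call"),
                                  levels = BEHAVIOR_LEVELS),
                    stringsAsFactors = FALSE)
  out$up_times <- lapply(res, `[[`, "up_times")
  out$down_times <- lapply(res, `[[`, "down_times")
  class(out) <- c("tf_calls", "data.frame")
  out
}

#' Cross-tabulate behavior calls of the two lineages
#'
#' Builds the 4x4 contingency table of genes by (adipocyte call, osteoblast
#' call), with categories in fixed order UP, DOWN, UP_DOWN, UNCHANGED (rows:
#' adipocyte; columns: osteoblast).
#'
#' @param calls_osteo,calls_adipo `tf_calls` data.frames covering the same
#'   gene set, one call per gene per lineage.
#' @return A `crosstab4` list: `cells` (4x4 integer matrix), `row_totals`,
#'   `col_totals`, `grand_total`.
#' @export
cross_tabulate <- function(calls_osteo, calls_adipo) {
  only_o <- setdiff(calls_osteo$gene_id, calls_adipo$gene_id)
  only_a <- setdiff(calls_adipo$gene_id, calls_osteo$gene_id)
  if (length(only_o) + length(only_a) > 0L) {
    stop("gene(s) present in one lineage only: ",
         paste(utils::head(c(only_o, only_a), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(calls_osteo$gene_id) || anyDuplicated(calls_adipo$gene_id)) {
    stop("duplicate gene_id in calls", call. = FALSE)
  }
  o <- factor(as.character(calls_osteo$call), levels = BEHAVIOR_LEVELS)
  names(o) <- calls_osteo$gene_id
  a <- factor(as.character(calls_adipo$call), levels = BEHAVIOR_LEVELS)
  names(a) <- calls_adipo$gene_id
  cells <- table(adipocyte = a, osteoblast = o[names(a)])
  crosstab_from_cells(unclass(cells))
}

#' Build a `crosstab4` from raw 4x4 cell counts
#'
#' @param cells 4x4 numeric matrix of non-negative counts; rows are adipocyte
#'   calls, columns osteoblast calls, both in order UP, DOWN, UP_DOWN,
#'   UNCHANGED.
#' @return A `crosstab4` list with marginals populated.
#' @export
crosstab_from_cells <- function(cells) {
  cells <- as.matrix(cells)
  stopifnot(all(dim(cells) == c(4L, 4L)), all(cells >= 0))
  storage.mode(cells) <- "integer"
  dimnames(cells) <- list(adipocyte = BEHAVIOR_LEVELS,
                          osteoblast = BEHAVIOR_LEVELS)
  structure(list(cells = cells,
                 row_totals = rowSums(cells),
                 col_totals = colSums(cells),
                 grand_total = sum(cells)),
            class = "crosstab4")
}

#' Number of regulated genes in a cross-tabulation
#'
#' Genes up- or down-regulated in at least one lineage: the grand total minus
#' the (UNCHANGED, UNCHANGED) cell.
#'
#' @param table A `crosstab4`.
#' @return Integer count.
#' @export
count_changed <- function(table) {
  stopifnot(inherits(table, "crosstab4"))
  as.integer(table$grand_total - table$cells["UNCHANGED", "UNCHANGED"])
}

#' Candidate lineage-switch genes
#'
#' Genes with a pure opposite behavior in the two lineages: exactly UP in the
#' osteoblast course and exactly DOWN in the adipocyte course (or the
#' reverse). UP_DOWN calls are excluded.
#'
#' @param calls_osteo,calls_adipo `tf_calls` covering the same genes.
#' @param direction Length-2 character vector `c(osteoblast_call,
#'   adipocyte_call)`; either `c("UP","DOWN")` (default) or `c("DOWN","UP")`.
#' @return Character vector of gene ids, sorted for determinism.
#' @export
candidate_switch_genes <- function(calls_osteo, calls_adipo,
                                   direction = c("UP", "DOWN")) {
  stopifnot(length(direction) == 2L,
            all(direction %in% c("UP", "DOWN")), direction[1] != direction[2])
  o <- calls_osteo$gene_id[as.character(calls_osteo$call) == direction[1]]
  a <- calls_adipo$gene_id[as.character(calls_adipo$call) == direction[2]]
  sort(intersect(o, a))
}
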