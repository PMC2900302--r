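toy_dataset <- function(expr, times_ost = c(24, 48), times_ad = 24) {
  samples <- c("ctrl", sprintf("o%d", seq_along(times_ost)),
               sprintf("a%d", seq_along(times_ad)))
  colnames(expr) <- samples
  meta <- data.frame(
    sample_id = samples,
    lineage = c("control", rep("osteoblast", length(times_ost)),
                rep("adipocyte", length(times_ad))),
    time_hours = c(0, times_ost, times_ad),
    is_control = c(1L, integer(length(times_ost) + length(times_ad))))
  structure(list(expr = expr, meta = meta), class = "tf_dataset")
}

test_that("ratios are control-subtracted log2 intensities", {
  expr <- matrix(c(8, 8, 8, 8,     # flat gene
                   8, 10, 7, 9,    # moving gene
                   5, 5.5, 6, 4),  # third gene
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
  ds <- toy_dataset(expr)
  r <- compute_ratios(ds, "osteoblast")
  expect_equal(r$times, c(24, 48))
  # hand subtraction, all six entries
  expect_equal(unname(r$values),
               matrix(c(0, 0, 2, -1, 0.5, 1), nrow = 3, byrow = TRUE))
  expect_equal(unname(compute_ratios(ds, "adipocyte")$values[, 1]),
               c(0, 1, -1))
})

test_that("ratio preconditions are enforced", {
  expr <- matrix(8, nrow = 1, ncol = 4, dimnames = list("g1", NULL))
  ds <- toy_dataset(expr)
  no_ctrl <- ds
  no_ctrl$meta$is_control <- 0L
  expect_error(compute_ratios(no_ctrl, "osteoblast"), "control")
  dup <- ds
  dup$meta$time_hours[3] <- 24  # second osteoblast sample at the same time
  expect_error(compute_ratios(dup, "osteoblast"), "duplicate")
  expect_error(compute_ratios(ds, "chondrocyte"), "no samples")
})

test_that("per-time-point bounds use the population standard deviation", {
  expect_equal(per_timepoint_bounds(c(3, 3, 3), k = 3),
               c(lower = 3, upper = 3))
  b <- per_timepoint_bounds(c(0, 0, 0, 4), k = 3)
  expect_equal(unname(b), c(1 - 3 * sqrt(3), 1 + 3 * sqrt(3)))
  expect_equal(per_timepoint_bounds(c(1, 5), k = 0), c(lower = 3, upper = 3))
  expect_error(per_timepoint_bounds(4, k = 3), "at least 2")
})

test_that("single-gene classification follows the threshold-or-bounds rule", {
  wide_lo <- rep(-10, 3)
  wide_hi <- rep(10, 3)
  times <- c(1, 24, 48)
  expect_equal(classify_gene(c(0, 0, 0), times, wide_lo, wide_hi)$call,
               "UNCHANGED")
  up <- classify_gene(c(1.5, 2, 1.2), times, wide_lo, wide_hi)
  expect_equal(up$call, "UP")
  expect_equal(up$up_times, times)
  both <- classify_gene(c(1.2, -1.3, 0), times, wide_lo, wide_hi)
  expect_equal(both$call, "UP_DOWN")
  expect_equal(both$up_times, 1)
  expect_equal(both$down_times, 24)
  # ties at the threshold do not fire (strictly greater than)
  expect_equal(classify_gene(c(1, -1, 1), times, wide_lo, wide_hi)$call,
               "UNCHANGED")
  # the array-adaptive bound fires even below the fold threshold
  expect_equal(classify_gene(c(0.5, 0, 0), times, wide_lo, c(0.4, 10, 10))$call,
               "UP")
  expect_error(classify_gene(c(0, 0), times, wide_lo, wide_hi), "equal length")
})

test_that("classification agrees with naive enumeration on all 125 patterns", {
  vals <- c(-2, -1.2, 0, 1.2, 2)
  lower <- c(-1.5, -3, -1.1)
  upper <- c(1.5, 3, 1.1)
  times <- c(1, 2, 3)
  grid <- expand.grid(a = vals, b = vals, c = vals)
  for (i in seq_len(nrow(grid))) {
    v <- as.numeric(grid[i, ])
    expect_identical(classify_gene(v, times, lower, upper)$call,
                     oracle_classify(v, lower, upper))
  }
})

test_that("a huge sd multiplier reduces to the pure fold-threshold rule", {
  set.seed(11)
  times <- 1:6
  for (rep in 1:25) {
    m <- matrix(stats::rnorm(60, sd = 1.5), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
    ratios <- structure(list(lineage = "osteoblast", times = times,
                             values = m), class = "tf_ratios")
    calls <- classify_lineage(ratios, classification_params(sd_multiplier = 1e9))
    pure <- apply(m, 1, function(v) {
      if (any(v > 1) && any(v < -1)) "UP_DOWN"
      else if (any(v > 1)) "UP" else if (any(v < -1)) "DOWN" else "UNCHANGED"
    })
    expect_identical(as.character(calls$call), unname(pure))
  }
})

test_that("raising the fold threshold never creates a regulated call", {
  set.seed(13)
  times <- 1:5
  lower <- rep(-4, 5); upper <- rep(4, 5)
  for (rep in 1:50) {
    v <- stats::runif(5, -3, 3)
    lo <- classify_gene(v, times, lower, upper,
                        classification_params(fold_threshold = 0.8))
    hi <- classify_gene(v, times, lower, upper,
                        classification_params(fold_threshold = 1.6))
    if (lo$call == "UNCHANGED") expect_equal(hi$call, "UNCHANGED")
    expect_true(all(hi$up_times %in% lo$up_times))
    expect_true(all(hi$down_times %in% lo$down_times))
  }
})

test_that("classification is invariant to time-point permutation", {
  set.seed(17)
  times <- c(1, 6, 24, 48, 96)
  for (rep in 1:20) {
    v <- stats::runif(5, -2.5, 2.5)
    lower <- stats::runif(5, -3, -1)
    upper <- stats::runif(5, 1, 3)
    ref <- classify_gene(v, times, lower, upper)
    p <- sample(5)
    perm <- classify_gene(v[p], times[p], lower[p], upper[p])
    expect_identical(perm$call, ref$call)
    expect_identical(sort(perm$up_times), sort(ref$up_times))
    expect_identical(sort(perm$down_times), sort(ref$down_times))
  }
})

test_that("cross-tabulation counts genes by lineage-call pairs", {
  empty <- cross_tabulate(make_calls(character(0), character(0)),
                          make_calls(character(0), character(0), "adipocyte"))
  expect_equal(empty$grand_total, 0L)
  expect_true(all(empty$cells == 0L))

  osteo <- make_calls(c("a", "b", "c", "d", "e"),
                      c("UP", "DOWN", "DOWN", "UNCHANGED", "UNCHANGED"))
  adipo <- make_calls(c("a", "b", "c", "d", "e"),
                      c("UP", "UP", "DOWN", "UNCHANGED", "UNCHANGED"),
                      "adipocyte")
  tab <- cross_tabulate(osteo, adipo)
  expect_equal(tab$cells["UP", "UP"], 1L)
  expect_equal(tab$cells["UP", "DOWN"], 1L)
  expect_equal(tab$cells["DOWN", "DOWN"], 1L)
  expect_equal(tab$cells["UNCHANGED", "UNCHANGED"], 2L)
  expect_equal(sum(tab$cells), 5L)
  expect_equal(count_changed(tab), 3L)

  expect_error(cross_tabulate(osteo, adipo[-1, ]), "one lineage only")
})

test_that("published cross-tabulation cells reproduce through the pipeline type", {
  ref <- reference_crosstab()
  calls <- calls_from_cells(ref$cells)
  tab <- cross_tabulate(calls$osteo, calls$adipo)
  expect_identical(tab$cells, ref$cells)
  expect_equal(unname(tab$col_totals), c(92L, 77L, 34L, 1067L))
  expect_equal(unname(tab$row_totals), c(102L, 218L, 12L, 938L))
  expect_equal(tab$grand_total, 1270L)
  expect_equal(count_changed(tab), 407L)
})

test_that("cell conservation holds for random call sets", {
  set.seed(19)
  levels <- c("UP", "DOWN", "UP_DOWN", "UNCHANGED")
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    ids <- sprintf("g%04d", 1:n)
    tab <- cross_tabulate(make_calls(ids, sample(levels, n, TRUE)),
                          make_calls(ids, sample(levels, n, TRUE), "adipocyte"))
    expect_equal(sum(tab$cells), n)
    expect_equal(unname(rowSums(tab$cells)), unname(tab$row_totals))
    expect_equal(unname(colSums(tab$cells)), unname(tab$col_totals))
    expect_equal(count_changed(tab),
                 tab$grand_total - tab$cells["UNCHANGED", "UNCHANGED"])
  }
})

test_that("switch candidates are pure opposite calls, sorted", {
  osteo <- make_calls(c("z", "a", "b", "c", "d", "e"),
                      c("UP", "UP", "UP_DOWN", "DOWN", "UNCHANGED", "UP"))
  adipo <- make_calls(c("z", "a", "b", "c", "d", "e"),
                      c("DOWN", "DOWN", "DOWN", "UP", "UNCHANGED", "UNCHANGED"),
                      "adipocyte")
  expect_identical(candidate_switch_genes(osteo, adipo), c("a", "z"))
  expect_identical(candidate_switch_genes(osteo, adipo, c("DOWN", "UP")), "c")
  flat <- make_calls(c("x", "y"), c("UNCHANGED", "UNCHANGED"))
  flat_a <- make_calls(c("x", "y"), c("UNCHANGED", "UNCHANGED"), "adipocyte")
  expect_identical(candidate_switch_genes(flat, flat_a), character(0))
})
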