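fixture_ratios <- function(lineage = "osteoblast") {
  compute_ratios(build_reference_fixture(), lineage)
}

test_that("profile standardization z-scores across time", {
  expect_message(z <- standardize_profile(c(1, 1, 1)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_equal(standardize_profile(c(0, 2)), c(-1, 1))
  expect_equal(standardize_profile(c(1, 2, 3)),
               c(-1, 0, 1) / sqrt(2 / 3))  # population-SD z-score by hand
})

test_that("gene clustering is deterministic and groups identical profiles", {
  m <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                4, 3, 2, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  res <- cluster_genes(m, "euclidean", "average")
  expect_equal(min(res$merge_tree$height), 0)
  expect_setequal(res$gene_order, c("g1", "g2", "g3"))

  # two well-separated pairs: the first two merges are the pairs
  pairs <- rbind(c(0, 0, 0, 1), c(0, 0, 0.1, 1.1),
                 c(5, 5, 5, 6), c(5, 5, 5.1, 6.1))
  rownames(pairs) <- c("a1", "a2", "b1", "b2")
  res2 <- cluster_genes(pairs, "euclidean", "average")
  first_two <- res2$merge_tree$merge[1:2, ]
  expect_true(all(first_two < 0))
  merged <- apply(abs(first_two), 1, function(i)
    paste(sort(rownames(pairs)[i]), collapse = "+"))
  expect_setequal(merged, c("a1+a2", "b1+b2"))

  m[1, 1] <- NaN
  expect_error(cluster_genes(m), "non-finite")
})

test_that("fixture genes of one phase are contiguous in the heat-map order", {
  ro <- fixture_ratios()
  ord <- cluster_genes(ro, "correlation", "average")$gene_order
  for (members in fixture_phase_genes()) {
    pos <- sort(match(members, ord))
    expect_equal(pos, seq(min(pos), length.out = length(members)))
  }
})

test_that("phase assignment places peaks in the containing window", {
  w <- osteoblast_phase_windows()
  times <- default_time_grids()$osteoblast
  mk <- function(v) structure(list(lineage = "osteoblast", times = times,
                                   values = matrix(v, nrow = 1,
                                                   dimnames = list("g", NULL))),
                              class = "tf_ratios")
  up_at <- function(t, peak = 2) {
    v <- numeric(length(times)); v[times == t] <- peak; v
  }
  calls1 <- classify_lineage(mk(up_at(1)))
  a1 <- assign_phases(calls1, mk(up_at(1)), w)
  expect_equal(a1$window_label, "1h")
  expect_equal(a1$peak_time_hours, 1)
  expect_equal(a1$peak_value, 2)

  a120 <- assign_phases(classify_lineage(mk(up_at(120))), mk(up_at(120)), w)
  expect_equal(a120$window_label, "4-6d")

  # an UP_DOWN course yields one assignment per direction
  v <- up_at(1); v[times == 240] <- -2
  aud <- assign_phases(classify_lineage(mk(v)), mk(v), w)
  expect_setequal(aud$direction, c("UP", "DOWN"))
  expect_equal(aud$window_label[aud$direction == "UP"], "1h")
  expect_equal(aud$window_label[aud$direction == "DOWN"], "8-14d")

  # unchanged genes receive no assignment
  flat <- mk(numeric(length(times)))
  expect_equal(nrow(assign_phases(classify_lineage(flat), flat, w)), 0L)

  # a peak outside every window violates the coverage invariant
  narrow <- phase_windows("osteoblast", "1h", 0.5, 3)
  expect_error(assign_phases(classify_lineage(mk(up_at(120))),
                             mk(up_at(120)), narrow), "outside")
})

test_that("fixture Hey1 is assigned to the 6-24h osteoblast window", {
  ro <- fixture_ratios()
  calls <- classify_lineage(ro)
  asg <- assign_phases(calls, ro, osteoblast_phase_windows())
  hey1 <- asg[asg$gene_id == "Hey1" & asg$direction == "UP", ]
  expect_equal(hey1$window_label, "6-24h")
})

test_that("earliest time wins argmax ties", {
  times <- c(1, 3, 6)
  v <- c(2, 2, 0)
  mk <- structure(list(lineage = "osteoblast", times = times,
                       values = matrix(v, nrow = 1,
                                       dimnames = list("g", NULL))),
                  class = "tf_ratios")
  w <- phase_windows("osteoblast", c("early", "late"), c(0.5, 2), c(2, 6))
  a <- assign_phases(classify_lineage(mk), mk, w)
  expect_equal(a$peak_time_hours, 1)
  expect_equal(a$window_label, "early")
})

test_that("window detection finds block boundaries and spans the grid", {
  times <- c(1, 3, 6, 12, 24, 48)
  set.seed(23)
  u <- stats::runif(20, 1, 2)
  v <- stats::runif(20, 1, 2)
  m <- cbind(u, u, u, v, v, v) + matrix(stats::rnorm(120, sd = 0.01),
                                        nrow = 20)
  rownames(m) <- sprintf("g%02d", 1:20)
  colnames(m) <- NULL
  r <- structure(list(lineage = "osteoblast", times = times, values = m),
                 class = "tf_ratios")
  w <- detect_phase_windows(r, max_phases = 5)
  expect_equal(nrow(w), 2L)
  expect_true(w$end_hours[1] > 6 && w$end_hours[1] < 12)

  # identical columns collapse to a single window
  flat <- structure(list(lineage = "osteoblast", times = times,
                         values = matrix(rep(stats::runif(20), 6), ncol = 6,
                                         dimnames = list(sprintf("g%02d", 1:20),
                                                         NULL))),
                    class = "tf_ratios")
  expect_equal(nrow(detect_phase_windows(flat, max_phases = 4)), 1L)

  # partition property: windows are ordered, disjoint and cover every time
  for (win in list(w, detect_phase_windows(fixture_ratios(), 6))) {
    expect_true(all(diff(win$start_hours) > 0))
    expect_true(all(win$end_hours[-nrow(win)] == win$start_hours[-1]))
    covered <- vapply(times, function(t)
      t >= win$start_hours[1] && t <= win$end_hours[nrow(win)], logical(1))
    expect_true(all(covered))
  }
})

test_that("noiseless fixture sample structure yields the five osteoblast phases", {
  w <- detect_phase_windows(fixture_ratios(), max_phases = 6)
  expect_equal(nrow(w), 5L)
  # boundaries separate the same sample groups as the canonical windows
  grid <- default_time_grids()$osteoblast
  canonical <- osteoblast_phase_windows()
  expect_equal(findInterval(grid, w$start_hours),
               findInterval(grid, canonical$start_hours))
})

test_that("phase report counts and orders members per window", {
  w <- phase_windows("osteoblast", c("w1", "w2"), c(0.5, 10), c(10, 48))
  empty <- phase_report(
    assign_phases(make_calls(character(0), character(0)),
                  structure(list(lineage = "osteoblast", times = c(1, 24),
                                 values = matrix(numeric(0), nrow = 0)),
                            class = "tf_ratios"), w), w)
  expect_true(all(empty$n == 0L))
  expect_equal(nrow(empty), 4L)  # two windows x two directions

  asg <- data.frame(gene_id = c("g2", "g1", "g3"), lineage = "osteoblast",
                    direction = "UP", window_label = c("w1", "w1", "w2"),
                    peak_time_hours = c(1, 1, 24), peak_value = 2,
                    stringsAsFactors = FALSE)
  class(asg) <- c("phase_assignments", "data.frame")
  rep <- phase_report(asg, w)
  up <- rep[rep$direction == "UP", ]
  expect_equal(up$n, c(2L, 1L))
  expect_equal(up$members[[1]], c("g1", "g2"))  # peak tie broken by gene id
})

test_that("fixture phase membership is recovered exactly without noise", {
  ro <- fixture_ratios()
  calls <- classify_lineage(ro)
  asg <- assign_phases(calls, ro, osteoblast_phase_windows())
  up <- asg[asg$direction == "UP", ]
  labels <- fixture_phase_genes()
  expected <- rep(names(labels), lengths(labels))
  names(expected) <- unlist(labels, use.names = FALSE)
  expect_equal(nrow(up), 110L)
  expect_identical(stats::setNames(up$window_label, up$gene_id)[names(expected)],
                   expected)
})

test_that("phase recovery tolerates per-point Gaussian noise of sd 0.1", {
  cfg <- simulation_config(n_background_genes = 0, n_family_background = 0,
                           noise_sd_log2 = 0.1, seed = 271)
  ds <- generate_dataset(cfg)
  ro <- compute_ratios(ds, "osteoblast")
  asg <- assign_phases(classify_lineage(ro), ro, osteoblast_phase_windows())
  up <- asg[asg$direction == "UP", ]
  labels <- fixture_phase_genes()
  expected <- stats::setNames(rep(names(labels), lengths(labels)),
                              unlist(labels, use.names = FALSE))
  hit <- sum(stats::setNames(up$window_label, up$gene_id)[names(expected)] ==
             expected, na.rm = TRUE)
  expect_gte(hit / length(expected), 0.95)
})
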