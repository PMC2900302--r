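# Independent oracles and small builders shared across the suite.

# Naive re-statement of the behavior rule: walk the time points one by one and
# apply the verbatim criteria. Kept deliberately separate from classify_gene.
oracle_classify <- function(values, lower, upper, fold = 1) {
  n_up <- 0L
  n_down <- 0L
  for (i in seq_along(values)) {
    fired_up <- FALSE
    fired_down <- FALSE
    if (values[i] > fold) fired_up <- TRUE
    if (values[i] > upper[i]) fired_up <- TRUE
    if (values[i] < -fold) fired_down <- TRUE
    if (values[i] < lower[i]) fired_down <- TRUE
    if (fired_up) n_up <- n_up + 1L
    if (fired_down) n_down <- n_down + 1L
  }
  if (n_up > 0L && n_down > 0L) return("UP_DOWN")
  if (n_up > 0L) return("UP")
  if (n_down > 0L) return("DOWN")
  "UNCHANGED"
}

# Pearson chi-square via the expected-count expansion sum((O - E)^2 / E).
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expected)^2 / expected)
}

# Minimal behavior-call table for cross-tabulation / switch-candidate tests.
make_calls <- function(gene_id, call, lineage = "osteoblast") {
  out <- data.frame(gene_id = gene_id,
                    lineage = rep(lineage, length(gene_id)),
                    call = factor(call,
                                  levels = c("UP", "DOWN", "UP_DOWN",
                                             "UNCHANGED")),
                    stringsAsFactors = FALSE)
  out$up_times <- rep(list(numeric(0)), nrow(out))
  out$down_times <- rep(list(numeric(0)), nrow(out))
  class(out) <- c("tf_calls", "data.frame")
  out
}

# Expand a crosstab's cells into matched per-lineage call vectors.
calls_from_cells <- function(cells) {
  levels <- c("UP", "DOWN", "UP_DOWN", "UNCHANGED")
  adipo <- character(0)
  osteo <- character(0)
  for (i in 1:4) {
    for (j in 1:4) {
      k <- cells[i, j]
      adipo <- c(adipo, rep(levels[i], k))
      osteo <- c(osteo, rep(levels[j], k))
    }
  }
  ids <- sprintf("g%04d", seq_along(adipo))
  list(osteo = make_calls(ids, osteo, "osteoblast"),
       adipo = make_calls(ids, adipo, "adipocyte"))
}

write_catalog_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\tsymbol\tgo_ids\tinterpro_ids", lines), path)
  path
}
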