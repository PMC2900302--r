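#' Pearson chi-square test of independence for a 2x2 table
#'
#' Closed form `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with one degree
#' of freedom; the p-value is the upper-tail chi-square(1) probability. No
#' continuity correction by default (`correct = TRUE` applies the Yates
#' correction).
#'
#' @param a,b,c,d Non-negative cell counts: `a` in-phase and in-family, `b`
#'   in-phase not in-family, `c` in-family not in-phase, `d` neither.
#' @param correct Apply the Yates continuity correction. Default `FALSE`.
#' @return List with `chi2`, `df` (always 1) and `p_value`.
#' @export
chi_square_independence <- function(a, b, c, d, correct = FALSE) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  n <- sum(cells)
  if (n <= 0) stop("degenerate table: empty", call. = FALSE)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate table: zero marginal", call. = FALSE)
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / prod(margins)
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Family-by-phase enrichment test
#'
#' Tests over-representation of a gene family among the members of one
#' temporal phase, against the full array background, with a 2x2 chi-square
#' test of independence (df = 1, no continuity correction by default).
#'
#' @param phase_members Character vector of gene ids assigned to the phase.
#' @param family Character vector of family member gene ids.
#' @param background Character vector of all background gene ids (the whole
#'   catalog standing in for the array universe). Both `phase_members` and
#'   `family` must be subsets of it.
#' @param alpha Significance level; default 0.01.
#' @param family_name,phase_label Labels carried into the result.
#' @param correct Yates continuity correction flag, passed through.
#' @return One-row `enrichment_result` data.frame: `family`, `phase_label`,
#'   `a`, `b`, `c`, `d`, `chi2`, `df`, `p_value`, `significant`.
#' @export
enrich <- function(phase_members, family, background, alpha = 0.01,
                   family_name = "family", phase_label = "phase",
                   correct = FALSE) {
  bad_p <- setdiff(phase_members, background)
  bad_f <- setdiff(family, background)
  if (length(bad_p) + length(bad_f) > 0L) {
    stop("ids outside the background: ",
         paste(utils::head(c(bad_p, bad_f), 5), collapse = ", "),
         call. = FALSE)
  }
  phase_members <- unique(phase_members)
  family <- unique(family)
  background <- unique(background)
  a <- length(intersect(phase_members, family))
  b <- length(phase_members) - a
  cc <- length(family) - a
  d <- length(background) - length(phase_members) - cc
  test <- chi_square_independence(a, b, cc, d, correct = correct)
  out <- data.frame(family = family_name, phase_label = phase_label,
                    a = a, b = b, c = cc, d = d,
                    chi2 = test$chi2, df = test$df, p_value = test$p_value,
                    significant = test$p_value < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment of every family in every phase
#'
#' Runs [enrich()] for each (phase window, family) pair using the
#' up-regulated members of each phase (phase membership follows the
#' up-regulated gene lists of the phase summary), ordered by lineage, then
#' window, then family. No multiple-testing adjustment is applied by default;
#' `bonferroni = TRUE` multiplies p-values by the number of tests (capped at
#' 1) before the significance call.
#'
#' @param report A `phase_report` (per-lineage); its UP rows define phase
#'   membership.
#' @param families List of [family_definition()] objects.
#' @param catalog The `tf_catalog` whose gene ids form the background.
#' @param alpha Significance level; default 0.01.
#' @param correct Yates continuity correction flag.
#' @param bonferroni Bonferroni-adjust across the (phase, family) tests.
#' @return An `enrichment_result` data.frame, one row per (phase, family),
#'   with a leading `lineage` column.
#' @export
enrich_all <- function(report, families, catalog, alpha = 0.01,
                       correct = FALSE, bonferroni = FALSE) {
  background <- catalog$gene_id
  up <- report[report$direction == "UP", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(up))) {
    for (fam in families) {
      fam_ids <- family_members(catalog, fam)
      res <- tryCatch(
        enrich(up$members[[i]], fam_ids, background, alpha = alpha,
               family_name = fam$name, phase_label = up$window_label[i],
               correct = correct),
        error = function(e) {
          # degenerate table (empty phase or family spanning everything):
          # report the cells with NA statistic rather than aborting the scan
          a <- length(intersect(up$members[[i]], fam_ids))
          data.frame(family = fam$name, phase_label = up$window_label[i],
                     a = a, b = length(unique(up$members[[i]])) - a,
                     c = length(fam_ids) - a,
                     d = length(unique(background)) -
                       length(unique(up$members[[i]])) - length(fam_ids) + a,
                     chi2 = NA_real_, df = 1L, p_value = NA_real_,
                     significant = FALSE, stringsAsFactors = FALSE)
        })
      res <- cbind(lineage = up$lineage[i], res)
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(lineage = character(0), family = character(0),
                      phase_label = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      chi2 = numeric(0), df = integer(0),
                      p_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  if (bonferroni) {
    out$p_value <- pmin(1, out$p_value * nrow(out))
    out$significant <- out$p_value < alpha
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
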