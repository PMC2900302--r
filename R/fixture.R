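#' Osteoblast phase-specific up-regulated gene lists of the reference study
#'
#' The 110 transcription-factor symbols up-regulated during osteoblast
#' differentiation of ST2 cells, grouped by the five clustering-derived phases
#' (46 + 29 + 4 + 7 + 24 genes), in chronological cluster order as printed.
#'
#' @return Named list mapping window label (`"1h"`, `"6-24h"`, `"30-48h"`,
#'   `"4-6d"`, `"8-14d"`) to an ordered character vector of gene symbols.
#' @export
fixture_phase_genes <- function() {
  list(
    "1h" = c("Foxc2", "Nfatc1", "Hoxb2", "Fkhl18", "Med14", "Id4", "Msx2",
             "Id2", "Ankrd1", "Hes1", "Bhlhe40", "Foxn1", "Tle4", "Hmga2",
             "Dlx3", "Gata2", "Dlx2", "Nr4a3", "Axud1", "Eaf1", "Hipk2",
             "AC153948.5", "Zfx", "Cebpb", "Grhl1", "Smad7", "Rel", "Maff",
             "Mafk", "Klf16", "Id1", "Nfil3", "Fosl1", "Klf5", "Npas4",
             "Lmcd1", "Atf3", "Fosb", "Mef2c", "Erf", "Mef2a", "Atp6v0a1",
             "Srf", "Tgif1", "Nr4a1", "Junb"),
    "6-24h" = c("Hey1", "Atoh8", "Helb", "Hdac9", "Atf6", "Gcom1", "Hoxa1",
                "Prrx1", "Tgfb1", "Creb3l1", "Rbm9", "Elk3", "C1d", "Dlx1",
                "Pde8a", "Hey2", "Ets2", "Dtna", "Smad6", "Foxo1", "Cux1",
                "Gatad2b", "Irf5", "Rfc1", "Sp7", "Arnt2", "Aebp1", "Hoxc13",
                "Aff3"),
    "30-48h" = c("Lef1", "Fabp4", "Stat5a", "Prrx2"),
    "4-6d" = c("Hod", "Maf", "Foxf2", "Sox9", "Stat1", "Foxd1", "Neo1"),
    "8-14d" = c("Stat2", "Esr1", "Klf9", "Klf13", "AC162313.5", "Cml3",
                "Pou6f1", "Pura", "Nfat5", "Zfp521", "Trib3", "Ddit3",
                "2210012G02Rik", "Clock", "Irf7", "Nr3c1", "Irf9", "Zhx2",
                "Sqstm1", "Znfx1", "Atf5", "Hoxa9", "Nr1d2", "Nfe2l1")
  )
}

#' The eleven profiled bHLH transcription factors
#'
#' Behavior arrows and cluster labels of the eleven bHLH-superfamily
#' transcription factors followed through both differentiation courses in the
#' reference study. `adipocyte_cluster` is `NA` for genes unchanged during
#' adipocyte differentiation.
#'
#' @return Data.frame with columns `symbol`, `osteoblast_call`,
#'   `adipocyte_call`, `osteoblast_cluster`, `adipocyte_cluster`.
#' @export
fixture_bhlh_table <- function() {
  data.frame(
    symbol = c("Bhlhe40", "Hes1", "Id1", "Id2", "Id4", "Npas4", "Arnt2",
               "Atoh8", "Hey1", "Hey2", "Clock"),
    osteoblast_call = c("UP", "UP", "UP_DOWN", "UP_DOWN", "UP", "UP_DOWN",
                        "UP", "UP_DOWN", "UP", "UP", "UP"),
    adipocyte_call = c("DOWN", "DOWN", "DOWN", "DOWN", "DOWN", "DOWN",
                       "UNCHANGED", "DOWN", "UNCHANGED", "UNCHANGED", "UP"),
    osteoblast_cluster = c("1h", "1h", "1h", "1h", "1h", "1h", "6-24h",
                           "6-24h", "6-24h", "6-24h", "8-14d"),
    adipocyte_cluster = c("4d", "4d", "10-14d", "2d", "4d", "2d", NA,
                          "2d", NA, NA, "10-14d"),
    stringsAsFactors = FALSE
  )
}

#' Candidate molecular-switch genes of the reference study
#'
#' The bHLH genes two-fold or greater up-regulated during osteoblast
#' differentiation and one-half fold or greater down-regulated during
#' adipocyte differentiation.
#'
#' @return Character vector of three gene symbols.
#' @export
fixture_switch_genes <- function() {
  c("Bhlhe40", "Hes1", "Id4")
}

#' Reference cross-tabulation of 1,270 transcription factors
#'
#' The published 4x4 cross-tabulation of behavior calls (rows: adipocyte;
#' columns: osteoblast; order UP, DOWN, UP_DOWN, UNCHANGED) for the 1,270
#' transcription factors of the ST2 differentiation study, as a worked-example
#' input for marginal and changed-gene arithmetic.
#'
#' @return A `crosstab4`; see [crosstab_from_cells()].
#' @export
reference_crosstab <- function() {
  crosstab_from_cells(matrix(c(
    22,  6,  4,  70,
    25, 40, 21, 132,
     3,  5,  2,   2,
    42, 26,  7, 863
  ), nrow = 4, byrow = TRUE))
}

#' Default sampling grids of the two differentiation courses
#'
#' Fifteen osteoblast and seven adipocyte sampling times (hours after
#' induction, excluding the shared time-0 control), spanning 1 h to 14 d.
#'
#' @return Named list with numeric vectors `osteoblast` and `adipocyte`.
#' @export
default_time_grids <- function() {
  list(osteoblast = c(1, 3, 6, 12, 18, 24, 30, 36, 48, 96, 120, 144, 192,
                      240, 336),
       adipocyte = c(2, 24, 48, 96, 168, 240, 336))
}

# Grid time closest to the midpoint of a labeled window (earliest on ties).
window_peak_time <- function(label, windows, times) {
  i <- match(label, windows$label)
  if (is.na(i)) stop("unknown window label: ", label, call. = FALSE)
  in_w <- vapply(times, function(t) identical(window_index(t, windows), i),
                 logical(1))
  cand <- times[in_w]
  if (length(cand) == 0L) stop("window ", label, " contains no grid time",
                               call. = FALSE)
  mid <- (windows$start_hours[i] + windows$end_hours[i]) / 2
  cand[which.min(abs(cand - mid))]
}

# Regulated profile over a grid: +/-amplitude at the peak grid time of the
# labeled window, a sub-threshold shoulder (0.4 * amplitude) at the window's
# other grid times, zero outside.
window_profile <- function(label, windows, times, amplitude, sign = 1) {
  i <- match(label, windows$label)
  peak <- window_peak_time(label, windows, times)
  v <- numeric(length(times))
  in_w <- vapply(times, function(t) identical(window_index(t, windows), i),
                 logical(1))
  v[in_w] <- sign * 0.4 * amplitude
  v[times == peak] <- sign * amplitude
  v
}

# Unchanged profile: +/- amplitude with a deterministic per-(gene, time) sign,
# sub-threshold everywhere. The signs are desynchronized across genes and
# times (a synchronized wiggle would shrink the per-time-point array variance
# toward zero and shift its mean off zero, letting flat genes cross the
# mean +/- 3SD bound, and would imprint an artificial correlation pattern on
# the sample columns).
unchanged_profile <- function(times, amplitude, gene_index = 1L) {
  s <- ((gene_index * 48271 + seq_along(times) * 16807) %% 97) %% 2
  amplitude * (2 * s - 1)
}

#' Build the deterministic reference fixture dataset
#'
#' A noiseless two-lineage dataset realizing the printed gene-list structure
#' of the reference study: the 110 phase-labeled osteoblast up-regulated
#' transcription factors ([fixture_phase_genes()]) peak (+`peak_amplitude`
#' log2, default 2, i.e. four-fold) at the grid time nearest the midpoint of
#' their labeled phase window, with sub-threshold shoulders elsewhere in the
#' window; the eleven bHLH genes ([fixture_bhlh_table()]) additionally realize
#' their adipocyte arrows on the adipocyte grid (DOWN as a mirrored negative
#' profile in the labeled cluster window, UNCHANGED as alternating +/-0.2);
#' osteoblast UP_DOWN genes carry a sustained -`updown_amplitude` log2 dip
#' across the last osteoblast window. All fixture genes carry GO:0003700; the
#' eleven bHLH genes carry InterPro IPR001092. Expression is emitted as log2
#' intensities around a flat baseline of 8 with a shared time-0 control, so
#' that ratio computation is exercised end to end. Output is deterministic.
#'
#' @param peak_amplitude,updown_amplitude,unchanged_amplitude Log2 amplitudes
#'   of the regulated peak, the UP_DOWN downward dip, and the unchanged
#'   wiggle. Defaults 2, 1.5 and 0.2.
#' @return A `tf_dataset` list: `expr` (log2 intensity matrix, genes x
#'   samples), `meta` (sample metadata: `sample_id`, `lineage`, `time_hours`,
#'   `is_control`), `catalog` (a `tf_catalog`).
#' @export
build_reference_fixture <- function(peak_amplitude = 2,
                                    updown_amplitude = 1.5,
                                    unchanged_amplitude = 0.2) {
  grids <- default_time_grids()
  w_ost <- osteoblast_phase_windows()
  w_ad <- adipocyte_phase_windows()
  phases <- fixture_phase_genes()
  bhlh <- fixture_bhlh_table()
  genes <- unlist(phases, use.names = FALSE)
  stopifnot(!anyDuplicated(genes), all(bhlh$symbol %in% genes))

  last_ost <- nrow(w_ost)
  dip_times <- vapply(grids$osteoblast,
                      function(t) identical(window_index(t, w_ost), last_ost),
                      logical(1))
  ost <- matrix(0, nrow = length(genes), ncol = length(grids$osteoblast),
                dimnames = list(genes, NULL))
  ad <- matrix(0, nrow = length(genes), ncol = length(grids$adipocyte),
               dimnames = list(genes, NULL))
  for (lab in names(phases)) {
    for (g in phases[[lab]]) {
      ost[g, ] <- window_profile(lab, w_ost, grids$osteoblast, peak_amplitude)
    }
  }
  for (i in seq_len(nrow(bhlh))) {
    g <- bhlh$symbol[i]
    if (bhlh$osteoblast_call[i] == "UP_DOWN") {
      ost[g, dip_times] <- -updown_amplitude
    }
    ad[g, ] <- switch(bhlh$adipocyte_call[i],
      DOWN = window_profile(bhlh$adipocyte_cluster[i], w_ad, grids$adipocyte,
                            peak_amplitude, sign = -1),
      UP = window_profile(bhlh$adipocyte_cluster[i], w_ad, grids$adipocyte,
                          peak_amplitude, sign = 1),
      UNCHANGED = unchanged_profile(grids$adipocyte, unchanged_amplitude,
                                    gene_index = match(g, genes)))
  }
  plain <- setdiff(genes, bhlh$symbol)
  for (g in plain) {
    ad[g, ] <- unchanged_profile(grids$adipocyte, unchanged_amplitude,
                                 gene_index = match(g, genes))
  }

  catalog <- new_catalog(
    gene_id = genes, symbol = genes,
    go_ids = rep(list("GO:0003700"), length(genes)),
    interpro_ids = lapply(genes, function(g) {
      if (g %in% bhlh$symbol) "IPR001092" else character(0)
    })
  )
  assemble_dataset(ost, ad, grids, catalog)
}

# Stack ratio matrices into a log2-intensity tf_dataset around a baseline of 8
# with one shared time-0 control sample.
assemble_dataset <- function(ost_ratios, ad_ratios, grids, catalog,
                             baseline = NULL) {
  genes <- rownames(ost_ratios)
  if (is.null(genes)) genes <- character(0)
  stopifnot(nrow(ost_ratios) == nrow(ad_ratios),
            identical(genes, rownames(ad_ratios) %||% character(0)),
            identical(genes, catalog$gene_id))
  if (is.null(baseline)) baseline <- rep(8, length(genes))
  samples <- c("ctrl_0h",
               sprintf("ost_%gh", grids$osteoblast),
               sprintf("ad_%gh", grids$adipocyte))
  expr <- cbind(baseline, baseline + ost_ratios, baseline + ad_ratios)
  dimnames(expr) <- list(genes, samples)
  meta <- data.frame(
    sample_id = samples,
    lineage = c("control", rep("osteoblast", length(grids$osteoblast)),
                rep("adipocyte", length(grids$adipocyte))),
    time_hours = c(0, grids$osteoblast, grids$adipocyte),
    is_control = c(1L, integer(length(grids$osteoblast) +
                               length(grids$adipocyte))),
    stringsAsFactors = FALSE
  )
  structure(list(expr = expr, meta = meta, catalog = catalog),
            class = "tf_dataset")
}
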