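#' Simulation configuration
#'
#' Parameters of the seeded synthetic-data generator. Amplitudes are log2
#' ratios; the unchanged amplitude must stay below the classification fold
#' threshold so background genes are sub-threshold by construction.
#'
#' @param n_background_genes Number of unregulated array-background genes.
#' @param n_family_background Number of background genes tagged with the bHLH
#'   InterPro domain (IPR001092), emulating the family's array-wide
#'   representation.
#' @param peak_amplitude_log2 Peak log2 ratio of regulated fixture genes
#'   (default 2, i.e. four-fold, so the two-fold switch criterion is met with
#'   margin).
#' @param updown_amplitude_log2 Magnitude of the downward dip of UP_DOWN
#'   genes (default 1.5).
#' @param unchanged_amplitude_log2 Half-width of the uniform unchanged
#'   wiggle (default 0.2).
#' @param noise_sd_log2 Standard deviation of Gaussian log2 noise added to
#'   every non-control expression value (default 0, noiseless).
#' @param seed Integer seed; a fixed seed makes [generate_dataset()] output
#'   byte-identical across runs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_background_genes = 20000,
                              n_family_background = 100,
                              peak_amplitude_log2 = 2,
                              updown_amplitude_log2 = 1.5,
                              unchanged_amplitude_log2 = 0.2,
                              noise_sd_log2 = 0,
                              seed = 1) {
  stopifnot(n_background_genes >= 0, n_family_background >= 0,
            n_family_background <= n_background_genes,
            peak_amplitude_log2 > 0, updown_amplitude_log2 > 0,
            unchanged_amplitude_log2 > 0, noise_sd_log2 >= 0)
  structure(list(n_background_genes = as.integer(n_background_genes),
                 n_family_background = as.integer(n_family_background),
                 peak_amplitude_log2 = peak_amplitude_log2,
                 updown_amplitude_log2 = updown_amplitude_log2,
                 unchanged_amplitude_log2 = unchanged_amplitude_log2,
                 noise_sd_log2 = noise_sd_log2,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic two-lineage dataset
#'
#' Background genes get unchanged profiles (log2 ratios uniform in plus/minus
#' the unchanged amplitude) on both sampling grids; `n_family_background` of
#' them carry InterPro IPR001092 (family members that are not transcription
#' factors, emulating the family's representation across the whole array).
#' The reference fixture genes are appended unless `include_fixture = FALSE`.
#' Gaussian log2 noise of sd `noise_sd_log2` is then added to every
#' non-control expression value. Output is reproducible: the generator is a
#' pure function of the configuration.
#'
#' @param config A [simulation_config()].
#' @param include_fixture Append the [build_reference_fixture()] genes.
#' @return A `tf_dataset`; see [build_reference_fixture()].
#' @export
generate_dataset <- function(config = simulation_config(),
                             include_fixture = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  grids <- default_time_grids()
  n <- config$n_background_genes
  amp <- config$unchanged_amplitude_log2
  bg_ids <- if (n > 0) sprintf("bg%05d", seq_len(n)) else character(0)
  ost <- matrix(stats::runif(n * length(grids$osteoblast), -amp, amp),
                nrow = n, ncol = length(grids$osteoblast),
                dimnames = list(bg_ids, NULL))
  ad <- matrix(stats::runif(n * length(grids$adipocyte), -amp, amp),
               nrow = n, ncol = length(grids$adipocyte),
               dimnames = list(bg_ids, NULL))
  bg_catalog <- new_catalog(
    gene_id = bg_ids, symbol = bg_ids,
    go_ids = rep(list(character(0)), n),
    interpro_ids = lapply(seq_len(n), function(i) {
      if (i <= config$n_family_background) "IPR001092" else character(0)
    })
  )
  if (include_fixture) {
    fx <- build_reference_fixture(
      peak_amplitude = config$peak_amplitude_log2,
      updown_amplitude = config$updown_amplitude_log2,
      unchanged_amplitude = config$unchanged_amplitude_log2)
    fx_ost <- fx$expr[, sprintf("ost_%gh", grids$osteoblast), drop = FALSE] -
      fx$expr[, "ctrl_0h"]
    fx_ad <- fx$expr[, sprintf("ad_%gh", grids$adipocyte), drop = FALSE] -
      fx$expr[, "ctrl_0h"]
    ost <- rbind(ost, fx_ost)
    ad <- rbind(ad, fx_ad)
    catalog <- new_catalog(
      gene_id = c(bg_catalog$gene_id, fx$catalog$gene_id),
      symbol = c(bg_catalog$symbol, fx$catalog$symbol),
      go_ids = c(bg_catalog$go_ids, fx$catalog$go_ids),
      interpro_ids = c(bg_catalog$interpro_ids, fx$catalog$interpro_ids))
  } else {
    catalog <- bg_catalog
  }
  ds <- assemble_dataset(ost, ad, grids, catalog)
  if (config$noise_sd_log2 > 0) {
    sample_cols <- ds$meta$sample_id[ds$meta$is_control == 0L]
    noise <- matrix(stats::rnorm(nrow(ds$expr) * length(sample_cols),
                                 sd = config$noise_sd_log2),
                    nrow = nrow(ds$expr))
    ds$expr[, sample_cols] <- ds$expr[, sample_cols] + noise
  }
  ds
}

#' Write a dataset to a directory of TSV files
#'
#' Emits `expression_osteoblast.tsv` and `expression_adipocyte.tsv` (gene_id
#' plus the shared control column plus the lineage's samples, log2
#' intensities), `metadata.tsv` (`sample_id`, `lineage`, `time_hours`,
#' `is_control`) and `annotation.tsv` (catalog format of [load_catalog()]).
#' Numeric values are written with 17 significant digits so the round trip
#' through [read_dataset()] is lossless.
#'
#' @param dataset A `tf_dataset`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- dataset$meta
  ctrl <- meta$sample_id[meta$is_control == 1L]
  paths <- c(expression_osteoblast = file.path(dir, "expression_osteoblast.tsv"),
             expression_adipocyte = file.path(dir, "expression_adipocyte.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  for (lin in c("osteoblast", "adipocyte")) {
    cols <- c(ctrl, meta$sample_id[meta$lineage == lin & meta$is_control == 0L])
    m <- dataset$expr[, cols, drop = FALSE]
    df <- data.frame(gene_id = rownames(m) %||% character(0),
                     stringsAsFactors = FALSE)
    for (j in seq_along(cols)) {
      df[[cols[j]]] <- formatC(m[, j], digits = 17, format = "g")
    }
    utils::write.table(df, paths[[paste0("expression_", lin)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(meta, paths[["metadata"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_catalog(dataset$catalog, paths[["annotation"]])
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the four TSV files.
#' @return A `tf_dataset`.
#' @export
read_dataset <- function(dir) {
  read_dataset_files(
    expression_osteoblast = file.path(dir, "expression_osteoblast.tsv"),
    expression_adipocyte = file.path(dir, "expression_adipocyte.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    annotation = file.path(dir, "annotation.tsv"))
}

#' Assemble a dataset from individual input files
#'
#' Entry point for user-supplied data in the package's TSV formats: two
#' per-lineage expression tables sharing one control column, a sample
#' metadata sidecar and an annotation catalog.
#'
#' @param expression_osteoblast,expression_adipocyte Paths to expression TSVs
#'   (first column `gene_id`, remaining columns sample ids, log2 scale).
#' @param metadata Path to the metadata TSV.
#' @param annotation Path to the annotation TSV.
#' @return A `tf_dataset`.
#' @export
read_dataset_files <- function(expression_osteoblast, expression_adipocyte,
                               metadata, annotation) {
  read_expr <- function(path) {
    if (!file.exists(path)) stop("expression file not found: ", path,
                                 call. = FALSE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, colClasses = "character")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df$gene_id
    m
  }
  m_ost <- read_expr(expression_osteoblast)
  m_ad <- read_expr(expression_adipocyte)
  if (!identical(rownames(m_ost), rownames(m_ad))) {
    stop("expression files disagree on gene ids", call. = FALSE)
  }
  shared <- intersect(colnames(m_ost), colnames(m_ad))
  if (length(shared) >= 1L &&
      !isTRUE(all.equal(m_ost[, shared], m_ad[, shared]))) {
    stop("shared control column(s) differ between expression files",
         call. = FALSE)
  }
  expr <- cbind(m_ost, m_ad[, setdiff(colnames(m_ad), shared), drop = FALSE])
  meta <- utils::read.delim(metadata, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "lineage", "time_hours", "is_control")
  if (!all(need %in% names(meta))) {
    stop("metadata lacks required column(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  }
  meta$is_control <- as.integer(meta$is_control)
  missing <- setdiff(meta$sample_id, colnames(expr))
  if (length(missing) > 0L) {
    stop("metadata sample(s) absent from expression: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  expr <- expr[, meta$sample_id, drop = FALSE]
  structure(list(expr = expr, meta = meta, catalog = load_catalog(annotation)),
            class = "tf_dataset")
}
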