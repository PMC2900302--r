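#' Pipeline configuration
#'
#' A single structured configuration drives a full run. Exactly one of
#' `inputs` (paths to the four TSV files) and `simulate` (the string
#' `"fixture"` or a [simulation_config()] / list of its fields) must be
#' given.
#'
#' @param inputs Named list with `expression_osteoblast`,
#'   `expression_adipocyte`, `metadata`, `annotation` paths, or `NULL`.
#' @param simulate `"fixture"`, a [simulation_config()], a list of
#'   [simulation_config()] fields, or `NULL`.
#' @param classification A [classification_params()] or list of its fields.
#' @param windows `"default"` (lineage defaults), or a named list with
#'   `osteoblast` / `adipocyte` [phase_windows()] data.frames.
#' @param families List of [family_definition()] objects (or lists with
#'   `name` / `interpro_id` / `explicit_members`); default the bHLH family by
#'   InterPro IPR001092.
#' @param go_terms GO accessions defining the transcription-factor universe;
#'   default [default_tf_go_terms()].
#' @param alpha Enrichment significance level, in (0,1); default 0.01.
#' @param correct Yates continuity correction for the enrichment chi-square.
#' @param bonferroni Bonferroni adjustment across enrichment tests.
#' @param outdir Output directory.
#' @param seed Integer seed governing all randomness of the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            classification = classification_params(),
                            windows = "default",
                            families = list(family_definition(
                              "bHLH", interpro_id = "IPR001092")),
                            go_terms = default_tf_go_terms(),
                            alpha = 0.01, correct = FALSE, bonferroni = FALSE,
                            outdir = NULL, seed = 1) {
  if (is.null(inputs) == is.null(simulate)) {
    stop("exactly one of inputs / simulate must be given", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  if (is.list(classification) && !inherits(classification,
                                           "classification_params")) {
    classification <- do.call(classification_params, classification)
  }
  if (!is.null(simulate) && !identical(simulate, "fixture") &&
      !inherits(simulate, "simulation_config")) {
    simulate <- do.call(simulation_config, as.list(simulate))
  }
  families <- lapply(families, function(f) {
    if (inherits(f, "family_definition")) f else do.call(family_definition, f)
  })
  structure(list(inputs = inputs, simulate = simulate,
                 classification = classification, windows = windows,
                 families = families, go_terms = go_terms, alpha = alpha,
                 correct = correct, bonferroni = bonferroni,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), character(0))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$windows) && !identical(raw$windows, "default")) {
    raw$windows <- lapply(stats::setNames(nm = names(raw$windows)),
                          function(lin) {
      w <- raw$windows[[lin]]
      phase_windows(lin, vapply(w, `[[`, "", "label"),
                    vapply(w, function(x) as.numeric(x$start_hours), 0),
                    vapply(w, function(x) as.numeric(x$end_hours), 0))
    })
  }
  do.call(pipeline_config, raw)
}

pipeline_output_files <- function(outdir) {
  file.path(outdir, c("behavior_calls.tsv", "contingency.tsv",
                      "contingency.json", "phase_membership.tsv",
                      "enrichment.tsv", "switch_candidates.tsv",
                      "run_report.json", "run.log"))
}

#' Run the full analysis pipeline
#'
#' Executes annotation loading, transcription-factor selection, ratio
#' computation, behavior classification, cross-lineage contingency, phase
#' assignment, family enrichment and switch-candidate extraction, writing all
#' TSV/JSON outputs plus a machine-readable run report. A stage failure
#' aborts with the stage name and removes partial outputs. Runs are
#' idempotent given the seed.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @param stop_after Run only the leading stages: `"classify"` stops after
#'   the cross-tabulation, `"phases"` after the phase report, `"enrich"` and
#'   `"all"` (default) run everything.
#' @return The run report, invisibly: a list with `counts`, `config`,
#'   `versions`, `outputs` and `log` entries.
#' @export
run_pipeline <- function(config, stop_after = c("all", "classify", "phases",
                                                "enrich")) {
  stop_after <- match.arg(stop_after)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (is.null(outdir)) stop("config must set an output directory",
                            call. = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(pipeline_output_files(outdir))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  set.seed(config$seed)
  note("seed: ", config$seed)

  dataset <- stage("input", {
    if (identical(config$simulate, "fixture")) {
      note("input: deterministic reference fixture")
      build_reference_fixture()
    } else if (inherits(config$simulate, "simulation_config")) {
      cfg <- config$simulate
      note("input: simulated dataset (n_background=", cfg$n_background_genes,
           ", n_family_background=", cfg$n_family_background,
           ", noise_sd=", cfg$noise_sd_log2, ", seed=", cfg$seed, ")")
      generate_dataset(cfg)
    } else {
      note("input: files ", paste(unlist(config$inputs), collapse = ", "))
      do.call(read_dataset_files, config$inputs)
    }
  })

  tfs <- stage("tf-selection", {
    sel <- select_transcription_factors(dataset$catalog, config$go_terms)
    if (length(sel) == 0L) {
      stop("no transcription factors selected from the annotation catalog")
    }
    note("tf-selection: ", length(sel), " transcription factors from ",
         length(config$go_terms), " GO terms")
    sel
  })

  params <- config$classification
  note("classification: fold_threshold=", params$fold_threshold,
       ", sd_multiplier=", params$sd_multiplier,
       " (array-wide per-time-point mean +/- k*SD bounds, population SD)")
  lineages <- c("osteoblast", "adipocyte")
  ratios <- list(); calls <- list()
  for (lin in lineages) {
    ratios[[lin]] <- stage("ratios", compute_ratios(dataset, lin))
    calls[[lin]] <- stage("classification",
                          classify_lineage(ratios[[lin]], params, genes = tfs))
  }
  crosstab <- stage("contingency",
                    cross_tabulate(calls$osteoblast, calls$adipocyte))
  switch_updown <- stage("switch-candidates",
                         candidate_switch_genes(calls$osteoblast,
                                                calls$adipocyte,
                                                c("UP", "DOWN")))

  windows <- list(); assignments <- list(); reports <- list()
  enrichment <- NULL
  if (stop_after != "classify") {
    for (lin in lineages) {
      windows[[lin]] <- stage("phases", {
        if (identical(config$windows, "default")) {
          note("phases: default ", lin, " windows")
          if (lin == "osteoblast") osteoblast_phase_windows()
          else adipocyte_phase_windows()
        } else {
          note("phases: configured ", lin, " windows")
          config$windows[[lin]]
        }
      })
      assignments[[lin]] <- stage("phases",
        assign_phases(calls[[lin]], ratios[[lin]], windows[[lin]]))
      reports[[lin]] <- stage("phases",
        phase_report(assignments[[lin]], windows[[lin]]))
    }
    if (stop_after != "phases") {
      enrichment <- stage("enrichment", {
        note("enrichment: alpha=", config$alpha,
             ", yates_correction=", config$correct,
             ", bonferroni=", config$bonferroni,
             ", background=whole catalog (", nrow(dataset$catalog), " genes)")
        do.call(rbind, lapply(lineages, function(lin) {
          enrich_all(reports[[lin]], config$families, dataset$catalog,
                     alpha = config$alpha, correct = config$correct,
                     bonferroni = config$bonferroni)
        }))
      })
    }
  }

  report <- stage("outputs", {
    write_pipeline_outputs(outdir, calls, crosstab, switch_updown,
                           assignments, reports, enrichment,
                           config, dataset, log_lines)
  })
  invisible(report)
}

write_pipeline_outputs <- function(outdir, calls, crosstab, switch_updown,
                                   assignments, reports, enrichment,
                                   config, dataset, log_lines) {
  fmt_times <- function(x) vapply(x, paste, "", collapse = ";")
  symbols <- stats::setNames(dataset$catalog$symbol, dataset$catalog$gene_id)

  calls_df <- data.frame(
    gene_id = calls$osteoblast$gene_id,
    symbol = unname(symbols[calls$osteoblast$gene_id]),
    osteoblast_call = as.character(calls$osteoblast$call),
    adipocyte_call = as.character(calls$adipocyte$call[
      match(calls$osteoblast$gene_id, calls$adipocyte$gene_id)]),
    osteoblast_up_times = fmt_times(calls$osteoblast$up_times),
    osteoblast_down_times = fmt_times(calls$osteoblast$down_times),
    adipocyte_up_times = fmt_times(calls$adipocyte$up_times[
      match(calls$osteoblast$gene_id, calls$adipocyte$gene_id)]),
    adipocyte_down_times = fmt_times(calls$adipocyte$down_times[
      match(calls$osteoblast$gene_id, calls$adipocyte$gene_id)]),
    stringsAsFactors = FALSE)
  utils::write.table(calls_df, file.path(outdir, "behavior_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cells <- crosstab$cells
  cont <- cbind(data.frame(adipocyte = rownames(cells)),
                as.data.frame.matrix(cells),
                Total = crosstab$row_totals)
  cont <- rbind(cont, c(adipocyte = "Total", as.list(crosstab$col_totals),
                        Total = crosstab$grand_total))
  utils::write.table(cont, file.path(outdir, "contingency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cells = cells, row_totals = crosstab$row_totals,
         col_totals = crosstab$col_totals, grand_total = crosstab$grand_total,
         changed = count_changed(crosstab)),
    file.path(outdir, "contingency.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")

  if (length(assignments) > 0L) {
    assign_df <- do.call(rbind, unname(assignments))
    assign_df <- cbind(assign_df,
                       symbol = unname(symbols[assign_df$gene_id]))
    assign_df <- assign_df[, c("lineage", "window_label", "gene_id", "symbol",
                               "direction", "peak_time_hours", "peak_value")]
    utils::write.table(assign_df, file.path(outdir, "phase_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(enrichment)) {
    utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(gene_id = switch_updown,
               symbol = unname(symbols[switch_updown])),
    file.path(outdir, "switch_candidates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(log_lines, file.path(outdir, "run.log"))

  per_phase <- lapply(reports, function(r) {
    data.frame(window_label = r$window_label, direction = r$direction,
               n = r$n, stringsAsFactors = FALSE)
  })
  report <- list(
    counts = list(
      n_genes = nrow(dataset$catalog),
      n_transcription_factors = nrow(calls$osteoblast),
      grand_total = crosstab$grand_total,
      changed = count_changed(crosstab),
      cells = crosstab$cells,
      per_phase = per_phase,
      n_enrichment_tests = if (is.null(enrichment)) 0L else nrow(enrichment),
      n_significant = if (is.null(enrichment)) 0L else
        sum(enrichment$significant),
      switch_candidates = switch_updown
    ),
    config = list(
      seed = config$seed, alpha = config$alpha,
      fold_threshold = config$classification$fold_threshold,
      sd_multiplier = config$classification$sd_multiplier,
      correct = config$correct, bonferroni = config$bonferroni,
      simulate = if (identical(config$simulate, "fixture")) "fixture"
                 else if (is.null(config$simulate)) "files"
                 else unclass(config$simulate)
    ),
    versions = list(tfcourse = as.character(utils::packageVersion("tfcourse")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    outputs = basename(pipeline_output_files(outdir)),
    log = log_lines
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  report
}
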