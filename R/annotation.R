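#' Load a gene annotation catalog from TSV
#'
#' Reads a tab-separated annotation table with columns `gene_id`, `symbol`,
#' `go_ids` and `interpro_ids` (the latter two semicolon-delimited, possibly
#' empty). One row per gene; the catalog replaces a genome-wide annotation
#' release so that user-supplied or synthetic catalogs can stand in for it.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A data.frame of class `tf_catalog` with columns `gene_id`, `symbol`
#'   (character) and `go_ids`, `interpro_ids` (list columns of character
#'   vectors; empty cells yield `character(0)`).
#' @details Duplicate `gene_id`s and malformed accessions (GO ids must match
#'   `GO:` followed by 7 digits, InterPro ids `IPR` followed by 6 digits) are
#'   hard errors naming the offending id or row.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  required <- c("gene_id", "symbol", "go_ids", "interpro_ids")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("annotation file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  new_catalog(df$gene_id, df$symbol,
              split_accessions(df$go_ids), split_accessions(df$interpro_ids))
}

split_accessions <- function(x) {
  lapply(x, function(cell) {
    cell <- trimws(cell)
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
  })
}

#' Construct a gene annotation catalog in memory
#'
#' @param gene_id,symbol Character vectors, one entry per gene.
#' @param go_ids,interpro_ids Lists of character vectors of accessions
#'   (`GO:\\d{7}` / `IPR\\d{6}`), one element per gene.
#' @return A `tf_catalog` data.frame; see [load_catalog()].
#' @export
new_catalog <- function(gene_id, symbol, go_ids, interpro_ids) {
  stopifnot(length(gene_id) == length(symbol),
            length(gene_id) == length(go_ids),
            length(gene_id) == length(interpro_ids))
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene_id in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  check_accessions(go_ids, "^GO:[0-9]{7}$", "GO")
  check_accessions(interpro_ids, "^IPR[0-9]{6}$", "InterPro")
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    stringsAsFactors = FALSE)
  out$go_ids <- unname(go_ids)
  out$interpro_ids <- unname(interpro_ids)
  class(out) <- c("tf_catalog", "data.frame")
  out
}

check_accessions <- function(acc_list, pattern, what) {
  for (i in seq_along(acc_list)) {
    bad <- acc_list[[i]][!grepl(pattern, acc_list[[i]])]
    if (length(bad) > 0L) {
      stop("malformed ", what, " accession in row ", i, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
}

#' Write an annotation catalog to TSV
#'
#' Inverse of [load_catalog()]: multi-valued columns are semicolon-joined so
#' that reloading yields an identical catalog.
#'
#' @param catalog A `tf_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(
    gene_id = catalog$gene_id,
    symbol = catalog$symbol,
    go_ids = vapply(catalog$go_ids, paste, "", collapse = ";"),
    interpro_ids = vapply(catalog$interpro_ids, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Default transcription-related GO term set
#'
#' The 39 transcription-related Gene Ontology accessions (GO release
#' 2009-01-25) used to define the transcription-factor universe; genes carrying
#' any of these terms are treated as transcription-factor-coding. Shipped as a
#' packaged data file, one accession per line.
#'
#' @return Character vector of 39 GO accessions.
#' @export
default_tf_go_terms <- function() {
  path <- system.file("extdata", "go_tf_terms.txt", package = "tfcourse",
                      mustWork = TRUE)
  readLines(path, warn = FALSE)
}

#' Select transcription-factor genes by GO annotation
#'
#' Returns the gene ids whose GO annotation intersects a flat set of
#' transcription-related GO accessions. Matching is by exact accession: there
#' is no propagation through the GO graph, mirroring selection against a fixed
#' printed term list.
#'
#' @param catalog A `tf_catalog`.
#' @param terms Character vector of GO accessions; defaults to
#'   [default_tf_go_terms()].
#' @return Sorted character vector of gene ids (possibly empty).
#' @export
select_transcription_factors <- function(catalog, terms = default_tf_go_terms()) {
  if (length(terms) == 0L) stop("GO term set must be non-empty", call. = FALSE)
  hit <- vapply(catalog$go_ids, function(g) any(g %in% terms), logical(1))
  sort(catalog$gene_id[hit])
}

#' Define a gene family
#'
#' A family is defined by an InterPro accession (all catalog genes carrying the
#' domain), an explicit member list, or both.
#'
#' @param name Family label, e.g. `"bHLH"`.
#' @param interpro_id Optional InterPro accession (`IPR` + 6 digits).
#' @param explicit_members Optional character vector of gene ids.
#' @return A `family_definition` list.
#' @export
family_definition <- function(name, interpro_id = NULL, explicit_members = NULL) {
  if (is.null(interpro_id) && is.null(explicit_members)) {
    stop("family definition needs an interpro_id or explicit_members",
         call. = FALSE)
  }
  if (!is.null(interpro_id) && !grepl("^IPR[0-9]{6}$", interpro_id)) {
    stop("malformed InterPro accession: ", interpro_id, call. = FALSE)
  }
  structure(list(name = name, interpro_id = interpro_id,
                 explicit_members = explicit_members),
            class = "family_definition")
}

#' Resolve family membership against a catalog
#'
#' Union of the catalog genes carrying the family's InterPro domain and the
#' explicit member list, restricted to the catalog. Explicit members absent
#' from the catalog are dropped with a warning.
#'
#' @param catalog A `tf_catalog`.
#' @param family A [family_definition()].
#' @return Sorted character vector of member gene ids.
#' @export
family_members <- function(catalog, family) {
  stopifnot(inherits(family, "family_definition"))
  members <- character(0)
  if (!is.null(family$interpro_id)) {
    hit <- vapply(catalog$interpro_ids,
                  function(x) family$interpro_id %in% x, logical(1))
    members <- catalog$gene_id[hit]
  }
  if (!is.null(family$explicit_members)) {
    absent <- setdiff(family$explicit_members, catalog$gene_id)
    if (length(absent) > 0L) {
      warning("explicit family member(s) absent from catalog, ignored: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    members <- union(members, intersect(family$explicit_members,
                                        catalog$gene_id))
  }
  sort(unique(members))
}
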