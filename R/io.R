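# All tables are TSV with a single header row; missing values are "NA"
# (read as missing, never as zero). Series-matrix-style files may carry
# "!"-prefixed comment lines before/around the table, which are skipped.

read_tsv_table <- function(path, comment = "!") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, comment)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("no table rows in ", path)
  tab <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                           na.strings = "NA", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  n_data_lines <- length(body) - 1L
  if (nrow(tab) != n_data_lines)
    stop(sprintf("parsed %d rows from %d data lines in %s: refusing to drop rows",
                 nrow(tab), n_data_lines, path))
  tab
}

tsv_to_matrix <- function(tab, path) {
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric values in matrix file ", path)
  rownames(m) <- ids
  m
}

#' Read an expression study from TSV files
#'
#' Expects probe x sample matrices (first column probe IDs, header row sample
#' IDs) for intensities and detection p-values, plus a design table with
#' columns `sample_id`, `group`, `tissue`, `study`, `animal_id`. Lines
#' starting with `!` (GEO series-matrix convention) are ignored, so the
#' sample-table block of a series-matrix-style file reads identically to a
#' plain TSV of the table body.
#'
#' @param path_intensity TSV of raw intensities.
#' @param path_detection_p TSV of detection p-values, or `NULL` if absent.
#' @param path_design TSV design table.
#' @param path_annotation optional TSV with columns `probe_id`, `symbol`.
#' @return a validated [expression_study()] with `scale = "raw"`; probe and
#'   sample order is preserved as given.
#' @export
read_expression_tsv <- function(path_intensity, path_detection_p, path_design,
                                path_annotation = NULL) {
  intens <- tsv_to_matrix(read_tsv_table(path_intensity), path_intensity)
  det <- NULL
  if (!is.null(path_detection_p)) {
    det <- tsv_to_matrix(read_tsv_table(path_detection_p), path_detection_p)
    if (!identical(dim(det), dim(intens)))
      stop(sprintf(
        "shape mismatch: intensity file has %d probes x %d samples, detection file has %d x %d",
        nrow(intens), ncol(intens), nrow(det), ncol(det)))
    if (!identical(rownames(det), rownames(intens)) ||
        !identical(colnames(det), colnames(intens)))
      stop("probe/sample IDs differ between intensity and detection files")
  }
  design <- read_tsv_table(path_design)
  in_matrix_only <- setdiff(colnames(intens), design$sample_id)
  if (length(in_matrix_only))
    stop("samples present in matrix but missing from design: ",
         paste(in_matrix_only, collapse = ", "))
  ann <- if (!is.null(path_annotation)) read_tsv_table(path_annotation) else NULL
  expression_study(intens, design, detection_p = det, scale = "raw",
                   annotation = ann)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a set are removed; empty sets are
#' rejected.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT parse error at line %d: set '%s' has no members",
                   i, fields[[1]]))
    sets[[fields[[1]]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], unique(sets[[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Floats are written with 15 significant digits so a write/read round trip
#' is the identity to well under 1e-9. Missing values are written as "NA".
#'
#' @param table data.frame with named columns.
#' @param path output path.
#' @export
write_results_tsv <- function(table, path) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(names(table)) || any(!nzchar(names(table))))
    stop("all table columns must be named")
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) {
    s <- formatC(x, digits = 15, format = "g")
    s[is.na(x)] <- NA
    s
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a results table written by [write_results_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  read_tsv_table(path)
}

#' Read a consumption table from TSV
#' @param path TSV with columns `animal_id`, `session`, `intake`, `study`.
#' @return a [consumption_table()].
#' @export
read_consumption_tsv <- function(path) {
  consumption_table(read_tsv_table(path))
}

#' Read a cell-type enrichment reference from TSV
#' @param path TSV with columns `symbol`, `cell_type`, `fold_enrichment`.
#' @return a [celltype_reference()].
#' @export
read_celltype_reference_tsv <- function(path) {
  celltype_reference(read_tsv_table(path))
}

#' Read a gene-symbol synonym map from TSV
#' @param path TSV with columns `alias`, `canonical`.
#' @return data.frame with those two columns.
#' @export
read_synonym_map_tsv <- function(path) {
  tab <- read_tsv_table(path)
  missing_cols <- setdiff(c("alias", "canonical"), names(tab))
  if (length(missing_cols))
    stop("synonym map is missing columns: ", paste(missing_cols, collapse = ", "))
  tab
}

#' Write an expression study to a directory of TSV files
#'
#' Inverse of [read_expression_tsv()]: writes `intensities.tsv`,
#' `detection_p.tsv` (if present), `design.tsv` and `annotation.tsv`
#' (if present) under `dir`.
#'
#' @param study an `expression_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_tsv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_df <- function(m) {
    data.frame(probe_id = rownames(m), m, check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  write_results_tsv(mat_df(study$intensities), file.path(dir, "intensities.tsv"))
  if (!is.null(study$detection_p))
    write_results_tsv(mat_df(study$detection_p), file.path(dir, "detection_p.tsv"))
  write_results_tsv(study$design, file.path(dir, "design.tsv"))
  if (!is.null(study$annotation))
    write_results_tsv(study$annotation, file.path(dir, "annotation.tsv"))
  invisible(dir)
}
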