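#' Construct an expression study
#'
#' The unit of data every pipeline stage consumes: a probe x sample intensity
#' matrix, an optional matching detection p-value matrix, and a per-sample
#' design table. Raw intensities must be finite and nonnegative; `scale`
#' records where in the preprocessing chain the values sit.
#'
#' @param intensities numeric matrix, probes in rows, samples in columns, with
#'   dimnames giving probe and sample IDs.
#' @param design data.frame with columns `sample_id`, `group` ("treated" or
#'   "control"), `tissue`, `study`, `animal_id`; one row per sample.
#' @param detection_p optional numeric matrix in `[0,1]`, same shape and
#'   dimnames as `intensities`. May be `NULL` after detection filtering.
#' @param scale one of "raw", "vst", "vst_quantile".
#' @param annotation optional data.frame with columns `probe_id`, `symbol`
#'   mapping probes to gene symbols (Illumina-style many probes to one gene).
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(intensities, design, detection_p = NULL,
                             scale = c("raw", "vst", "vst_quantile"),
                             annotation = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("`intensities` must carry probe IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(intensities)[duplicated(rownames(intensities))]),
               collapse = ", "))
  if (anyDuplicated(colnames(intensities)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(intensities)[duplicated(colnames(intensities))]),
               collapse = ", "))
  if (scale == "raw") {
    if (any(!is.finite(intensities)))
      stop("raw intensities must be finite")
    if (any(intensities < 0))
      stop("raw intensities must be nonnegative")
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(intensities)))
      stop(sprintf(
        "shape mismatch: intensities are %d x %d but detection p-values are %d x %d",
        nrow(intensities), ncol(intensities),
        nrow(detection_p), ncol(detection_p)))
    bad <- detection_p[is.finite(detection_p)]
    if (any(bad < 0 | bad > 1))
      stop("detection p-values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(intensities)
  }
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "tissue", "study", "animal_id")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols))
    stop("design table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("design table has duplicate sample IDs")
  orphans <- setdiff(colnames(intensities), design$sample_id)
  if (length(orphans))
    stop("samples present in matrix but missing from design: ",
         paste(orphans, collapse = ", "))
  if (!all(design$group %in% c("treated", "control")))
    stop('design `group` must be "treated" or "control"')
  # keep design in matrix column order, drop design rows without data
  design <- design[match(colnames(intensities), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(
    list(intensities = intensities, detection_p = detection_p,
         design = design, scale = scale, annotation = annotation),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d probes x %d samples (scale: %s)\n",
              nrow(x$intensities), ncol(x$intensities), x$scale))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$design$group)),
                            table(x$design$group)), collapse = ", ")))
  cat(sprintf("  detection p-values: %s\n",
              if (is.null(x$detection_p)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$intensities)

#' Column indices of the treated and control samples of a study
#' @param study an `expression_study`.
#' @return list with integer vectors `treated` and `control`.
#' @keywords internal
group_columns <- function(study) {
  list(treated = which(study$design$group == "treated"),
       control = which(study$design$group == "control"))
}

#' Drop samples from a study
#'
#' Removes columns (and their design rows) from every matrix the study holds.
#' Used after [flag_outlier_samples()] identifies arrays to discard.
#'
#' @param study an `expression_study`.
#' @param sample_ids character vector of sample IDs to remove.
#' @return the reduced `expression_study`.
#' @export
remove_samples <- function(study, sample_ids) {
  unknown <- setdiff(sample_ids, colnames(study$intensities))
  if (length(unknown))
    stop("cannot remove unknown samples: ", paste(unknown, collapse = ", "))
  keep <- !(colnames(study$intensities) %in% sample_ids)
  if (!any(keep)) stop("removal would leave no samples")
  study$intensities <- study$intensities[, keep, drop = FALSE]
  if (!is.null(study$detection_p))
    study$detection_p <- study$detection_p[, keep, drop = FALSE]
  study$design <- study$design[keep, , drop = FALSE]
  rownames(study$design) <- NULL
  study
}

#' Validate a consumption table
#'
#' Per-animal, per-session ethanol intake in g ethanol / kg body weight.
#' Sessions index ethanol-access days (intermittent paradigms have
#' non-drinking calendar days that carry no row).
#'
#' @param x data.frame with columns `animal_id`, `session`, `intake`, `study`.
#' @return the validated data.frame with class `consumption_table`.
#' @export
consumption_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("animal_id", "session", "intake", "study")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("consumption table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(x$intake)) || any(x$intake < 0))
    stop("intakes must be finite and nonnegative")
  by_animal <- split(x$session, x$animal_id)
  bad <- names(by_animal)[vapply(by_animal, function(s) any(diff(s) <= 0), logical(1))]
  if (length(bad))
    stop("sessions must be strictly increasing per animal; offending: ",
         paste(bad, collapse = ", "))
  class(x) <- c("consumption_table", "data.frame")
  x
}

#' Validate a cell-type enrichment reference
#'
#' @param x data.frame with columns `symbol`, `cell_type`, `fold_enrichment`.
#' @return validated data.frame with class `celltype_reference`.
#' @export
celltype_reference <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("symbol", "cell_type", "fold_enrichment")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("cell-type reference is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(x$fold_enrichment)) || any(x$fold_enrichment <= 0))
    stop("fold enrichment must be positive and finite")
  if (anyDuplicated(x[, c("symbol", "cell_type")]))
    stop("duplicate (symbol, cell type) pairs in reference")
  class(x) <- c("celltype_reference", "data.frame")
  x
}
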