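# Cell-type marker analysis: build cell-type-specific gene sets from an
# enrichment reference (4-fold criterion for brain, 10-fold for liver),
# then z-test each set's mean DE t-statistic against the study's
# cell-type-gene background.

#' Build cell-type-specific gene sets
#'
#' A gene belongs to a type's set iff its fold enrichment for that type is
#' at or above the threshold (inclusive boundary). Genes qualifying for
#' more than one type are not specific to any and are dropped from all
#' sets. Types left empty are skipped with a warning.
#'
#' @param reference a [celltype_reference()].
#' @param fold_threshold enrichment criterion, `> 1` (4 for brain, 10 for
#'   liver).
#' @return named list of character vectors (gene symbols) per cell type.
#' @export
build_celltype_sets <- function(reference, fold_threshold = 4) {
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  hits <- reference[reference$fold_enrichment >= fold_threshold, , drop = FALSE]
  if (!nrow(hits)) return(structure(list(), names = character()))
  multi <- unique(hits$symbol[duplicated(hits$symbol)])
  hits <- hits[!(hits$symbol %in% multi), , drop = FALSE]
  sets <- split(hits$symbol, hits$cell_type)
  empty <- setdiff(unique(reference$cell_type), names(sets))
  if (length(empty))
    warning("cell types with no specific genes skipped: ",
            paste(empty, collapse = ", "))
  lapply(sets, unique)
}

#' Harmonize gene symbols through a synonym map
#'
#' Maps aliases to their canonical symbol; symbols absent from the map pass
#' through unchanged and are counted. An alias mapping to two different
#' canonicals is an error.
#'
#' @param symbols character vector.
#' @param synonym_map data.frame with columns `alias`, `canonical`.
#' @return character vector of harmonized symbols with attribute
#'   `n_unmapped` (symbols not found in the map).
#' @export
harmonize_symbols <- function(symbols, synonym_map) {
  missing_cols <- setdiff(c("alias", "canonical"), names(synonym_map))
  if (length(missing_cols))
    stop("synonym map needs columns: ", paste(missing_cols, collapse = ", "))
  map <- unique(synonym_map[, c("alias", "canonical")])
  dup <- unique(map$alias[duplicated(map$alias)])
  if (length(dup))
    stop("ambiguous aliases mapping to multiple canonicals: ",
         paste(dup, collapse = ", "))
  idx <- match(symbols, map$alias)
  out <- ifelse(is.na(idx), symbols, map$canonical[idx])
  attr(out, "n_unmapped") <- sum(is.na(idx))
  out
}

#' z-test of cell-type set mean t-statistics
#'
#' Maps probes to gene symbols (multiple probes per gene collapse to the
#' probe with the largest `|t|`), pools all cell-type-specific genes
#' detected in the study as the background, and for each set computes
#' `z = (mean_t_set - mu0) / (sd_background / sqrt(n_set))` with a
#' two-sided normal p. The null mean `mu0` is the background mean t
#' (default) or 0; the background sd is common to all sets. Sets with
#' fewer than `min_set` detected genes are reported with `p = NA`.
#' Bonferroni adjustment multiplies by `bonferroni_factor` (by convention
#' the number of cell types times the number of studies in the tissue).
#'
#' @param de_table a `de_table` with per-probe `t`.
#' @param sets named list of gene-symbol sets from [build_celltype_sets()].
#' @param annotation data.frame `probe_id`, `symbol` mapping probes to
#'   genes.
#' @param null_mode "background_mean" (default) or "zero".
#' @param bonferroni_factor multiple-testing family size (default: number
#'   of sets).
#' @param min_set minimum detected set size (default 5).
#' @return data.frame of class `celltype_report`: `cell_type`, `n`,
#'   `mean_t`, `background_mean`, `background_sd`, `z`, `p`, `p_adjusted`.
#' @export
celltype_t_summary <- function(de_table, sets, annotation,
                               null_mode = c("background_mean", "zero"),
                               bonferroni_factor = NULL, min_set = 5) {
  null_mode <- match.arg(null_mode)
  if (is.null(bonferroni_factor)) bonferroni_factor <- length(sets)
  tab <- de_table[de_table$ok & !is.na(de_table$t), , drop = FALSE]
  tab$symbol <- annotation$symbol[match(tab$probe_id, annotation$probe_id)]
  tab <- tab[!is.na(tab$symbol), , drop = FALSE]
  # collapse multiple probes per gene to the largest |t|
  tab <- tab[order(-abs(tab$t)), , drop = FALSE]
  tab <- tab[!duplicated(tab$symbol), , drop = FALSE]

  in_any <- tab$symbol %in% unlist(sets, use.names = FALSE)
  bg_t <- tab$t[in_any]
  if (!length(bg_t)) {
    warning("no cell-type-specific genes detected in study")
    return(structure(data.frame(), class = c("celltype_report", "data.frame")))
  }
  bg_mean <- mean(bg_t)
  bg_sd <- stats::sd(bg_t)
  mu0 <- if (null_mode == "zero") 0 else bg_mean
  rows <- lapply(names(sets), function(ct) {
    t_set <- tab$t[tab$symbol %in% sets[[ct]]]
    n <- length(t_set)
    if (n < min_set) {
      return(data.frame(cell_type = ct, n = n,
                        mean_t = if (n) mean(t_set) else NA_real_,
                        background_mean = bg_mean, background_sd = bg_sd,
                        z = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                        stringsAsFactors = FALSE))
    }
    z <- if (bg_sd == 0) 0 else (mean(t_set) - mu0) / (bg_sd / sqrt(n))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(cell_type = ct, n = n, mean_t = mean(t_set),
               background_mean = bg_mean, background_sd = bg_sd,
               z = z, p = p, p_adjusted = min(1, p * bonferroni_factor),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "null_mode") <- null_mode
  class(out) <- c("celltype_report", "data.frame")
  out
}
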