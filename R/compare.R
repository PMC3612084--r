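# Cross-study comparison: DE-overlap testing on a shared detected-probe
# universe, direction concordance among shared DE genes, and the
# consumption-expression Pearson correlation screen.

#' Common detected-probe universe of two studies
#'
#' @param detected_a,detected_b character vectors of detected probe IDs.
#' @return character vector (intersection); `NULL` with a warning when the
#'   intersection is empty (the comparison is skipped).
#' @export
overlap_universe <- function(detected_a, detected_b) {
  if (!length(detected_a) || !length(detected_b))
    stop("both detected sets must be nonempty")
  common <- intersect(detected_a, detected_b)
  if (!length(common)) {
    warning("empty common universe: comparison skipped")
    return(NULL)
  }
  common
}

#' Chi-square test of DE overlap between two studies
#'
#' Builds the 2x2 table of DE-in-A by DE-in-B membership over a common
#' universe of `N` probes from the margins (`n1`, `n2`) and the observed
#' shared count `k`, and computes the goodness-of-fit statistic
#' `sum((O - E)^2 / E)` over the four cells against the
#' expected-under-independence counts (1 df, no continuity correction).
#' The expected shared count is `E = n1 * n2 / N`. When any expected cell
#' falls below 1 the chi-square approximation is unreliable and a
#' hypergeometric (Fisher-style upper tail at `k`) p-value is reported
#' instead, flagged in `method`.
#'
#' @param k observed shared DE count.
#' @param n1,n2 DE counts of the two studies within the universe.
#' @param N universe size.
#' @param bonferroni_factor number of pairwise tests in the family
#'   (default 6: the pairs among 4 studies within one tissue).
#' @return one-row data.frame: `N`, `n1`, `n2`, `k`, `expected`,
#'   `chi_square`, `p`, `p_adjusted`, `method`.
#' @export
overlap_test <- function(k, n1, n2, N, bonferroni_factor = 6) {
  if (n1 > N || n2 > N) stop("DE counts cannot exceed the universe")
  if (k > min(n1, n2)) stop("shared count cannot exceed either DE count")
  if (k < 0 || n1 < 0 || n2 < 0) stop("counts must be nonnegative")
  obs <- c(k, n1 - k, n2 - k, N - n1 - n2 + k)
  expd <- c(n1 * n2, n1 * (N - n2), (N - n1) * n2, (N - n1) * (N - n2)) / N
  if (any(expd < 1)) {
    # hypergeometric fallback: P(overlap >= k) under random draws
    p <- stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
    chi <- NA_real_
    method <- "hypergeometric"
  } else {
    chi <- sum((obs - expd)^2 / expd)
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    method <- "chi_square_gof"
  }
  data.frame(N = N, n1 = n1, n2 = n2, k = k, expected = expd[1],
             chi_square = chi, p = p,
             p_adjusted = min(1, p * bonferroni_factor),
             method = method, stringsAsFactors = FALSE)
}

#' Direction concordance of shared DE genes
#'
#' @param de_a,de_b `de_table`s (or data.frames with `probe_id` and
#'   `fold_change`).
#' @param shared character vector of shared DE probe IDs.
#' @return list: `same`, `opposite` (sum to `length(shared)` minus any
#'   zero-fold-change probes, which have no direction and are counted in
#'   `undirected`).
#' @export
direction_concordance <- function(de_a, de_b, shared) {
  if (!length(shared)) return(list(same = 0L, opposite = 0L, undirected = 0L))
  fa <- de_a$fold_change[match(shared, de_a$probe_id)]
  fb <- de_b$fold_change[match(shared, de_b$probe_id)]
  if (anyNA(fa) || anyNA(fb))
    stop("shared probes must appear in both DE tables")
  sa <- sign(fa); sb <- sign(fb)
  undirected <- sa == 0 | sb == 0
  list(same = sum(!undirected & sa == sb),
       opposite = sum(!undirected & sa != sb),
       undirected = sum(undirected))
}

#' Pairwise DE-overlap report across studies
#'
#' @param de_calls named list of [call_de()] results (one per study, same
#'   tissue); the detected universe of each study is its tested probe set.
#' @param bonferroni_factor family size; `NULL` uses the number of pairs.
#' @return data.frame, one row per pair, with overlap test columns plus
#'   `same_direction` and `opposite_direction`.
#' @export
overlap_report <- function(de_calls, bonferroni_factor = NULL) {
  stopifnot(length(de_calls) >= 2, !is.null(names(de_calls)))
  pairs <- utils::combn(names(de_calls), 2, simplify = FALSE)
  if (is.null(bonferroni_factor)) bonferroni_factor <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- de_calls[[pr[1]]]; b <- de_calls[[pr[2]]]
    det_a <- a$table$probe_id[a$table$ok]
    det_b <- b$table$probe_id[b$table$ok]
    universe <- overlap_universe(det_a, det_b)
    if (is.null(universe)) return(NULL)
    de_a <- intersect(a$table$probe_id[a$table$de], universe)
    de_b <- intersect(b$table$probe_id[b$table$de], universe)
    shared <- intersect(de_a, de_b)
    if (!length(de_a) || !length(de_b)) {
      res <- data.frame(N = length(universe), n1 = length(de_a),
                        n2 = length(de_b), k = 0L, expected = 0,
                        chi_square = NA_real_, p = NA_real_,
                        p_adjusted = NA_real_, method = "no_de",
                        stringsAsFactors = FALSE)
    } else {
      res <- overlap_test(length(shared), length(de_a), length(de_b),
                          length(universe),
                          bonferroni_factor = bonferroni_factor)
    }
    conc <- direction_concordance(a$table, b$table, shared)
    cbind(data.frame(study_a = pr[1], study_b = pr[2],
                     stringsAsFactors = FALSE),
          res,
          data.frame(same_direction = conc$same,
                     opposite_direction = conc$opposite))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Correlate total consumption with per-probe expression
#'
#' Pearson product-moment correlation between per-animal total intake and
#' each probe's expression, with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df. Complete-case per
#' probe (masked values dropped); probes with fewer than `min_n` pairs are
#' reported with `NA`. By default only drinking (treated) animals enter the
#' screen; `subset = "all_animals"` also uses controls, whose intake is 0
#' (they consume water), which conflates group effect with correlation and
#' is kept for comparison only.
#'
#' @param study preprocessed `expression_study`.
#' @param consumption a [consumption_table()] for the drinking animals.
#' @param subset "treated_only" (default) or "all_animals".
#' @param p_thresh significance threshold for the count (default 0.05).
#' @param min_n minimum complete-case n per probe (default 4).
#' @return list of class `correlation_screen`: `table` (probe_id, r, n, t,
#'   p, significant) and `n_significant`.
#' @export
correlate_consumption <- function(study, consumption,
                                  subset = c("treated_only", "all_animals"),
                                  p_thresh = 0.05, min_n = 4) {
  subset <- match.arg(subset)
  totals <- total_intake(consumption)$per_animal
  design <- study$design
  if (subset == "treated_only") {
    design <- design[design$group == "treated", , drop = FALSE]
  }
  intake <- totals$total[match(design$animal_id, totals$animal_id)]
  # animals absent from the table (water controls) consumed nothing
  intake[is.na(intake)] <- 0
  if (length(intake) < min_n) stop("too few animals for the screen")
  if (stats::sd(intake) == 0)
    stop("zero variance in total intake: correlation screen undefined")
  x <- study$intensities[, design$sample_id, drop = FALSE]
  n <- as.integer(rowSums(!is.na(x)))
  r <- suppressWarnings(as.vector(stats::cor(t(x), intake,
                                             use = "pairwise.complete.obs")))
  r[n < min_n] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmin(p, 1)
  tab <- data.frame(probe_id = rownames(x), r = r, n = n, t = tstat, p = p,
                    significant = !is.na(p) & p < p_thresh,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_significant = sum(tab$significant),
                 subset = subset, p_thresh = p_thresh),
            class = "correlation_screen")
}
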