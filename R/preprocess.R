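# Preprocessing chain, applied in this fixed order:
#   detection filter -> VST -> quantile normalization -> Grubbs screening
#   -> sample-level removal.
# Grubbs runs after normalization so flags are comparable across arrays,
# and within treatment group so a real treatment effect is never flagged.

#' Filter probes by detection p-value
#'
#' Retains probes detected (p <= `alpha`) on strictly more than `min_frac`
#' of the arrays; the surviving probe count is the study's "detected
#' transcripts" universe. The sample set is unchanged.
#'
#' @param study an `expression_study` with detection p-values.
#' @param alpha detection p-value cutoff (default 0.05).
#' @param min_frac minimum detected fraction of arrays, strict (default 0.8:
#'   a probe detected on exactly 80 percent of arrays is removed).
#' @return the filtered `expression_study`.
#' @export
detection_filter <- function(study, alpha = 0.05, min_frac = 0.8) {
  if (is.null(study$detection_p))
    stop("study has no detection p-values")
  frac <- rowMeans(study$detection_p <= alpha)
  keep <- frac > min_frac
  if (!any(keep))
    stop("no probes pass the detection filter: empty universe")
  study$intensities <- study$intensities[keep, , drop = FALSE]
  study$detection_p <- study$detection_p[keep, , drop = FALSE]
  if (!is.null(study$truth_index)) study$truth_index <- study$truth_index[keep]
  study
}

#' Fit the quadratic mean-variance model for the VST
#'
#' Computes per-probe mean and variance across arrays, smooths them into
#' intensity-ordered bins (median mean and median variance per bin), and
#' fits the quadratic by least squares on the relative scale (`Var/mean^2`
#' regressed on `1/mean^2` and `1/mean`). Binning keeps the per-probe
#' sampling noise of the variance (which grows with the variance itself)
#' from letting a handful of probes dominate the fit, and the relative
#' scale weights the intensity range evenly. Bead-level standard errors are
#' not available post hoc, so the across-array variance stands in for them.
#'
#' @param study raw-scale `expression_study` with >= 4 samples.
#' @param n_bins number of intensity bins (default 50, reduced for small
#'   studies; at least 10 fitted points are required).
#' @return list of class `vst_params`: `c1`, `c2`, `c3`, `r_squared`,
#'   `n_points` (bins fitted), and `fallback` (`TRUE` when the fitted `c3`
#'   is nonpositive or the binned variance shows no increasing trend in
#'   the mean, in which case [apply_vst()] uses `log2(x + 1)`).
#' @export
fit_vst <- function(study, n_bins = 50) {
  if (study$scale != "raw") stop("fit_vst expects a raw-scale study")
  if (ncol(study$intensities) < 4) stop("need >= 4 samples to fit the variance model")
  if (nrow(study$intensities) < 10)
    stop("need >= 10 probes to fit the variance model")
  mu <- rowMeans(study$intensities)
  v <- apply(study$intensities, 1, stats::var)
  keep <- mu > 0
  mu <- mu[keep]; v <- v[keep]
  n_bins <- max(10, min(n_bins, floor(length(mu) / 5)))
  if (length(mu) < 10) stop("need >= 10 usable (mean, variance) points")
  bin <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  mu_b <- tapply(mu, bin, stats::median)
  v_b <- tapply(v, bin, stats::median)
  rel <- v_b / mu_b^2
  fit <- stats::lm(rel ~ I(1 / mu_b^2) + I(1 / mu_b))
  cf <- unname(stats::coef(fit))
  c3 <- cf[1]
  # noise-driven negative c1/c2 estimates can make the fitted variance
  # function negative at the dim end; floor them so sigma^2(mu) stays
  # positive for all nonnegative intensities
  if (is.finite(c3) && c3 > 0) {
    vertex <- if (cf[3] < 0) -cf[3] / (2 * c3) else 0
    qmin <- c3 * vertex^2 + cf[3] * vertex + cf[2]
    if (!is.finite(qmin) || qmin <= 0) {
      cf[2] <- max(cf[2], 0)
      cf[3] <- max(cf[3], 0)
    }
  }
  # no stabilizing closed form when the fitted quadratic term is
  # nonpositive, or when the variance does not actually grow with the mean
  # (already-stable data: rank correlation of the binned mean-variance
  # trend near zero)
  trend <- stats::cor(mu_b, v_b, method = "spearman")
  fallback <- !is.finite(c3) || c3 <= 0 || !is.finite(trend) || trend < 0.5
  params <- list(c1 = cf[2], c2 = cf[3], c3 = c3,
                 r_squared = summary(fit)$r.squared,
                 n_points = length(mu_b),
                 fallback = fallback)
  class(params) <- "vst_params"
  params
}

#' Closed-form variance-stabilizing transform
#'
#' The antiderivative of `1/sigma(mu)` for the quadratic variance model
#' `sigma^2(mu) = c1 + c2*mu + c3*mu^2` with `c3 > 0`:
#' `h(x) = ln(2*sqrt(c3*(c3*x^2 + c2*x + c1)) + 2*c3*x + c2) / sqrt(c3)`,
#' defined up to an additive constant. [apply_vst()] rescales this affinely
#' onto the log2 range of the data.
#'
#' @param x intensity values.
#' @param c1,c2,c3 variance-model coefficients, `c3 > 0`.
#' @return transformed values.
#' @export
vst_transform <- function(x, c1, c2, c3) {
  if (c3 <= 0) stop("closed form requires c3 > 0")
  log(2 * sqrt(c3 * (c3 * x^2 + c2 * x + c1)) + 2 * c3 * x + c2) / sqrt(c3)
}

#' Apply the variance-stabilizing transformation
#'
#' Transforms raw intensities with the closed form
#' `h(x) = ln(2*sqrt(c3*(c3*x^2 + c2*x + c1)) + 2*c3*x + c2) / sqrt(c3)`
#' (the antiderivative of `1/sigma(mu)` for the fitted quadratic variance
#' model), then affinely rescales the result so that its range matches the
#' log2 of the raw data range, keeping downstream effects readable as log2
#' fold changes. When `c3 <= 0` the model has no stabilizing form and
#' `log2(x + 1)` is used instead (flagged in the params).
#'
#' @param study raw-scale `expression_study`.
#' @param params a `vst_params` object from [fit_vst()].
#' @return the transformed study with `scale = "vst"`; the transform is
#'   strictly increasing on the data range.
#' @export
apply_vst <- function(study, params) {
  if (study$scale != "raw") stop("apply_vst expects a raw-scale study")
  x <- study$intensities
  if (any(x < 0)) stop("negative intensity: VST domain error")
  if (params$fallback) {
    h <- log2(x + 1)
  } else {
    # noise-driven negative c1/c2 estimates can push the fitted variance
    # function below zero at the dim end; floor them rather than transform
    # into NaN there
    qmin <- min(params$c3 * x^2 + params$c2 * x + params$c1)
    if (!is.finite(qmin) || qmin <= 0) {
      params$c1 <- max(params$c1, 0)
      params$c2 <- max(params$c2, 0)
    }
    h <- vst_transform(x, params$c1, params$c2, params$c3)
    # align to the log2 scale of the raw data (lumi-style)
    lo_x <- max(min(x), 1); hi_x <- max(x)
    h_lo <- vst_transform(lo_x, params$c1, params$c2, params$c3)
    h_hi <- vst_transform(hi_x, params$c1, params$c2, params$c3)
    if (h_hi <= h_lo) stop("degenerate transform range")
    slope <- (log2(hi_x) - log2(lo_x)) / (h_hi - h_lo)
    h <- log2(lo_x) + (h - h_lo) * slope
  }
  study$intensities <- h
  study$scale <- "vst"
  study
}

#' Quantile-normalize a study
#'
#' Forces every sample column onto the common distribution given by the
#' row-wise mean of the column-sorted matrix. Ties within a column receive
#' the mean of the reference values at their tied ranks. Run before outlier
#' masking (no missing values allowed).
#'
#' @param study an `expression_study` with `scale = "vst"` (or raw, for
#'   standalone use).
#' @return study with identical column distributions, `scale =
#'   "vst_quantile"` when input was vst.
#' @export
quantile_normalize <- function(study) {
  x <- study$intensities
  if (anyNA(x)) stop("quantile normalization requires a complete matrix")
  if (ncol(x) == 1) {
    warning("single sample: quantile normalization is the identity")
    if (study$scale == "vst") study$scale <- "vst_quantile"
    return(study)
  }
  ref <- rowMeans(apply(x, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- x
  for (j in seq_len(ncol(x))) {
    # tied values share the mean of the reference values at their tied ranks
    lo <- rank(x[, j], ties.method = "min")
    hi <- rank(x[, j], ties.method = "max")
    col <- ref[lo]
    tied <- hi > lo
    if (any(tied))
      col[tied] <- (cs[hi[tied] + 1] - cs[lo[tied]]) / (hi[tied] - lo[tied] + 1)
    out[, j] <- col
  }
  study$intensities <- out
  if (study$scale == "vst") study$scale <- "vst_quantile"
  study
}

grubbs_critical <- function(n, critical_small, critical_large, n_switch) {
  if (n >= n_switch) critical_large else critical_small
}

#' Screen expression values with an iterated Grubbs test
#'
#' For each probe, within each design group separately, computes
#' `G = max |x_i - xbar| / s` and flags the most extreme value when `G`
#' exceeds the n-dependent critical value (2.21 for groups of up to 9
#' arrays, 2.29 for 10 or more, the two-sided alpha = 0.05 criticals at
#' those sizes), then repeats on the remaining values. At most
#' `max_removals` values are flagged per probe/group so the per-gene degrees
#' of freedom stay bounded; zero-variance groups are never flagged; groups
#' smaller than 3 are skipped.
#'
#' @param study a preprocessed `expression_study`.
#' @param critical_small,critical_large Grubbs critical values (defaults
#'   2.21 and 2.29).
#' @param n_switch group size at which `critical_large` takes over
#'   (default 10).
#' @param max_removals maximum flags per probe/group (default 2).
#' @return list of class `outlier_mask`: logical `mask` (probe x sample,
#'   `TRUE` = flagged) and `sample_fraction` (per-sample flagged fraction,
#'   the column means of the mask).
#' @export
grubbs_screen <- function(study, critical_small = 2.21, critical_large = 2.29,
                          n_switch = 10, max_removals = 2) {
  x <- study$intensities
  mask <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  groups <- split(seq_len(ncol(x)), study$design$group)
  skipped <- 0L
  for (cols in groups) {
    if (length(cols) < 3) { skipped <- skipped + 1L; next }
    sub <- x[, cols, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      vals <- sub[i, ]
      active <- which(!is.na(vals))
      removed <- 0L
      while (removed < max_removals && length(active) >= 3) {
        v <- vals[active]
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0) break
        dev <- abs(v - mean(v))
        g <- max(dev) / s
        crit <- grubbs_critical(length(active), critical_small,
                                critical_large, n_switch)
        if (g <= crit) break
        worst <- active[which.max(dev)]
        mask[i, cols[worst]] <- TRUE
        active <- setdiff(active, worst)
        removed <- removed + 1L
      }
    }
  }
  if (skipped > 0)
    warning(sprintf("%d group(s) with fewer than 3 samples skipped", skipped))
  structure(list(mask = mask, sample_fraction = colMeans(mask)),
            class = "outlier_mask")
}

#' Flag samples with too many outlier genes
#'
#' Returns the samples whose flagged-gene fraction strictly exceeds the
#' threshold (a sample at exactly the threshold is kept). The caller
#' decides whether to remove them via [remove_samples()].
#'
#' @param mask an `outlier_mask` from [grubbs_screen()].
#' @param threshold outlier-gene fraction above which a sample is flagged
#'   (default 0.05).
#' @return character vector of sample IDs.
#' @export
flag_outlier_samples <- function(mask, threshold = 0.05) {
  names(mask$sample_fraction)[mask$sample_fraction > threshold]
}

#' Mask flagged values as missing
#'
#' @param study an `expression_study`.
#' @param mask an `outlier_mask` of the same shape.
#' @return study with flagged intensities set to `NA` (handled downstream by
#'   complete-case per-gene fitting).
#' @export
apply_outlier_mask <- function(study, mask) {
  if (!identical(dim(mask$mask), dim(study$intensities)))
    stop("mask shape does not match study")
  study$intensities[mask$mask] <- NA
  study
}

#' Run the full preprocessing chain
#'
#' detection filter, VST, quantile normalization, Grubbs screening, removal
#' of samples whose flagged fraction exceeds `sample_outlier_frac`, and
#' masking of remaining flagged values.
#'
#' @param study raw `expression_study` with detection p-values.
#' @param alpha,min_frac detection-filter settings.
#' @param sample_outlier_frac sample-removal threshold (default 0.05).
#' @param critical_small,critical_large,n_switch Grubbs settings.
#' @return list: `study` (preprocessed, scale `vst_quantile`, flagged values
#'   `NA`), `vst_params`, `mask`, `removed_samples`, `n_detected` (the
#'   detected-transcript universe size).
#' @export
preprocess_study <- function(study, alpha = 0.05, min_frac = 0.8,
                             sample_outlier_frac = 0.05,
                             critical_small = 2.21, critical_large = 2.29,
                             n_switch = 10) {
  filtered <- detection_filter(study, alpha = alpha, min_frac = min_frac)
  params <- fit_vst(filtered)
  vst <- apply_vst(filtered, params)
  norm <- quantile_normalize(vst)
  mask <- grubbs_screen(norm, critical_small = critical_small,
                        critical_large = critical_large, n_switch = n_switch)
  removed <- flag_outlier_samples(mask, threshold = sample_outlier_frac)
  out <- norm
  if (length(removed)) {
    out <- remove_samples(out, removed)
    keep <- !(colnames(mask$mask) %in% removed)
    mask_applied <- mask
    mask_applied$mask <- mask$mask[, keep, drop = FALSE]
    mask_applied$sample_fraction <- mask$sample_fraction[keep]
    out <- apply_outlier_mask(out, mask_applied)
  } else {
    out <- apply_outlier_mask(out, mask)
  }
  list(study = out, vst_params = params, mask = mask,
       removed_samples = removed, n_detected = nrow(out$intensities))
}
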