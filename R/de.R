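# Two-group per-gene linear models with empirical-Bayes variance
# moderation (moderated t). The prior (d0, s0^2) is estimated by moment
# matching on log s^2 across genes; with d0 = 0 the stage reduces exactly
# to the ordinary pooled two-sample t, with d0 = Inf all gene variances
# are replaced by s0^2.

#' Fit the per-gene two-group model
#'
#' For each probe: effect `beta = mean(treated) - mean(control)` over the
#' available (non-masked) values, pooled residual variance `s2` and residual
#' degrees of freedom `df = n1 + n2 - 2`. Probes with fewer than 2 available
#' values in either group are flagged `ok = FALSE` with a reason and carry
#' `NA` estimates.
#'
#' @param study a preprocessed `expression_study` (masked values as `NA`).
#' @return data.frame: `probe_id`, `beta`, `s2`, `df`, `n1`, `n2`, `ok`,
#'   `reason`.
#' @export
fit_gene_models <- function(study) {
  gc <- group_columns(study)
  if (length(gc$treated) < 2 || length(gc$control) < 2)
    stop("need >= 2 samples per group")
  xt <- study$intensities[, gc$treated, drop = FALSE]
  xc <- study$intensities[, gc$control, drop = FALSE]
  n1 <- rowSums(!is.na(xt))
  n2 <- rowSums(!is.na(xc))
  m1 <- rowMeans(xt, na.rm = TRUE)
  m2 <- rowMeans(xc, na.rm = TRUE)
  ss1 <- rowSums((xt - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((xc - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  ok <- n1 >= 2 & n2 >= 2
  out <- data.frame(
    probe_id = rownames(study$intensities),
    beta = ifelse(ok, m1 - m2, NA_real_),
    s2 = ifelse(ok, (ss1 + ss2) / pmax(df, 1), NA_real_),
    df = ifelse(ok, df, NA_real_),
    n1 = n1, n2 = n2, ok = ok,
    reason = ifelse(ok, "", "fewer than 2 available values in a group"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0);
# trigamma is convex and decreasing so the iteration converges monotonely.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (-dif / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching on the log sample variances: with
#' `e_g = ln s2_g - digamma(d_g/2) + ln(d_g/2)`, solve
#' `trigamma(d0/2) = mean[(e_g - ebar)^2 * G/(G-1) - trigamma(d_g/2)]`
#' for the prior degrees of freedom `d0`, and set
#' `s0^2 = exp(ebar + digamma(d0/2) - ln(d0/2))`. When the trigamma target
#' is nonpositive (gene variances essentially homogeneous), `d0 = Inf` and
#' `s0^2 = exp(ebar)`.
#'
#' @param s2 vector of per-gene residual variances (zeros are floored to
#'   the smallest positive variance for the log-moment step).
#' @param df vector of per-gene residual degrees of freedom.
#' @return list of class `ebayes_prior`: `d0`, `s02`, `n_genes`.
#' @export
ebayes_prior <- function(s2, df) {
  keep <- is.finite(s2) & is.finite(df) & df > 0
  s2 <- s2[keep]; df <- df[keep]
  G <- length(s2)
  if (G < 50) stop("need >= 50 genes to estimate the prior")
  if (all(s2 == 0)) stop("all residual variances are zero: degenerate data")
  s2 <- pmax(s2, min(s2[s2 > 0]))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  target <- mean((e - ebar)^2 * G / (G - 1) - trigamma(df / 2))
  if (!is.finite(target) || target <= 0) {
    d0 <- Inf
    s02 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02, n_genes = G), class = "ebayes_prior")
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each gene variance toward the prior:
#' `s2_tilde = (d0*s02 + df*s2) / (d0 + df)`, then
#' `t = beta / sqrt(s2_tilde * (1/n1 + 1/n2))` with two-sided p-values from
#' the t distribution on `d0 + df` degrees of freedom. Forcing `d0 = 0`
#' recovers the ordinary pooled two-sample t exactly; `d0 = Inf` uses
#' `s02` for every gene and normal-tail p-values.
#'
#' @param fits data.frame from [fit_gene_models()].
#' @param prior an `ebayes_prior` (or a list with `d0`, `s02` to force a
#'   limit).
#' @return data.frame of class `de_table`: fit columns plus `s2_post`,
#'   `df_total`, `t`, `p`, `fdr` (Benjamini-Hochberg, informational),
#'   `fold_change`.
#' @export
moderated_t <- function(fits, prior) {
  d0 <- prior$d0; s02 <- prior$s02
  ok <- fits$ok
  if (is.infinite(d0)) {
    s2_post <- rep(s02, nrow(fits))
    df_total <- rep(Inf, nrow(fits))
  } else {
    s2_post <- (d0 * s02 + fits$df * fits$s2) / (d0 + fits$df)
    df_total <- d0 + fits$df
  }
  se <- sqrt(s2_post * (1 / fits$n1 + 1 / fits$n2))
  t <- fits$beta / se
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[ok & se == 0 & fits$beta == 0] <- 1
  t[ok & se == 0 & fits$beta == 0] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[!ok] <- NA
  out <- fits
  out$s2_post <- ifelse(ok, s2_post, NA_real_)
  out$df_total <- ifelse(ok, df_total, NA_real_)
  out$t <- ifelse(ok, t, NA_real_)
  out$p <- p
  out$fdr <- NA_real_
  out$fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  out$fold_change <- fold_change(out$beta)
  attr(out, "prior") <- prior
  class(out) <- c("de_table", "data.frame")
  out
}

#' Signed linear fold change from a log2 effect
#'
#' Treated relative to control: `+2^beta` for up-regulation, `-2^(-beta)`
#' for down-regulation, so `|FC| >= 1` and the sign carries direction.
#' `beta = 0` gives `+1`.
#'
#' @param beta log2-scale effect (vectorized).
#' @return signed fold change.
#' @export
fold_change <- function(beta) {
  ifelse(beta >= 0, 2^beta, -(2^(-beta)))
}

#' Call differentially expressed probes
#'
#' Flags probes with `p < p_thresh` (strict) and, when `fc_thresh` is given,
#' `|fold change| >= fc_thresh`. With `fc_thresh = NULL` this is the
#' detected-universe summary mode (raw p only); `fc_thresh = 1.2` is the
#' pathway-input mode.
#'
#' @param de_table a `de_table` from [moderated_t()].
#' @param p_thresh p-value threshold, strict (default 0.05).
#' @param fc_thresh fold-change magnitude floor, inclusive, or `NULL`.
#' @return list: `table` (input plus logical `de`), `summary` data.frame
#'   with `universe` (probes tested), `n_de`, `pct_de` (exact
#'   `100 * n_de / universe`) and `pct_label` (one decimal, e.g. "4.4%").
#' @export
call_de <- function(de_table, p_thresh = 0.05, fc_thresh = NULL) {
  ok <- de_table$ok & !is.na(de_table$p)
  de <- ok & de_table$p < p_thresh
  if (!is.null(fc_thresh))
    de <- de & abs(de_table$fold_change) >= fc_thresh
  de_table$de <- de
  universe <- sum(ok)
  n_de <- sum(de)
  pct <- 100 * n_de / universe
  list(table = de_table,
       summary = data.frame(universe = universe, n_de = n_de,
                            pct_de = pct,
                            pct_label = sprintf("%.1f%%", pct),
                            stringsAsFactors = FALSE))
}

#' Run the full differential-expression stage
#'
#' Fits per-gene models, estimates the variance prior, and calls DE. The
#' prior is estimated on genes with no masked values (outlier masking
#' trims extremes and biases the affected genes' sample variances
#' downward, which would drag `s0^2` below the truth); all genes are then
#' moderated toward that prior.
#'
#' @param study preprocessed `expression_study`.
#' @param d0_override force the prior degrees of freedom (0 for the
#'   classical pooled t, `Inf` for full shrinkage); default `NULL`
#'   estimates the prior from the data.
#' @param p_thresh,fc_thresh DE-calling thresholds, see [call_de()].
#' @return as [call_de()].
#' @export
de_analyze <- function(study, d0_override = NULL, p_thresh = 0.05,
                       fc_thresh = NULL) {
  fits <- fit_gene_models(study)
  usable <- fits$ok
  # outlier masking biases the trimmed genes' sample variances downward;
  # estimating the prior on complete-case genes keeps s0^2 unbiased
  complete <- usable & fits$df == max(fits$df[usable])
  prior_set <- if (sum(complete) >= 50) complete else usable
  prior <- ebayes_prior(fits$s2[prior_set], fits$df[prior_set])
  if (!is.null(d0_override)) {
    if (d0_override == 0) {
      prior$d0 <- 0
    } else {
      prior$d0 <- d0_override
    }
  }
  call_de(moderated_t(fits, prior), p_thresh = p_thresh,
          fc_thresh = fc_thresh)
}
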