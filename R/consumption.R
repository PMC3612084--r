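# Behavioral summaries of drinking data: per-animal totals, escalation
# (first-k vs last-k sessions, paired t), and between-group window
# comparisons. Sessions index ethanol-access days only.

#' Total ethanol intake per animal and per group
#'
#' @param consumption a [consumption_table()].
#' @return list: `per_animal` data.frame (`animal_id`, `study`, `total`,
#'   `n_sessions`) and `group_mean` (mean of per-animal totals, g/kg).
#'   Animals with no sessions are excluded with a warning upstream (they
#'   carry no rows by construction).
#' @export
total_intake <- function(consumption) {
  stopifnot(inherits(consumption, "consumption_table") ||
              all(c("animal_id", "intake") %in% names(consumption)))
  if (any(consumption$intake < 0)) stop("negative intake")
  agg <- stats::aggregate(intake ~ animal_id + study, data = consumption, FUN = sum)
  n <- stats::aggregate(intake ~ animal_id + study, data = consumption, FUN = length)
  per_animal <- data.frame(animal_id = agg$animal_id, study = agg$study,
                           total = agg$intake, n_sessions = n$intake,
                           stringsAsFactors = FALSE)
  list(per_animal = per_animal, group_mean = mean(per_animal$total))
}

#' Escalation of intake between first and last sessions
#'
#' Paired t-test on per-animal (last-`k` session mean minus first-`k`
#' session mean); the percent increase is computed on the group means of
#' the two windows, `100 * (last - first) / first`. Animals lacking a
#' complete window are dropped from the pairing. Flat data (all
#' differences 0) are reported with `t = 0`, `p = 1`.
#'
#' @param consumption a [consumption_table()].
#' @param k window length in sessions (default 4).
#' @return list of class `escalation_result`: `per_animal` (first/last
#'   window means and per-animal percent change), `percent_increase`,
#'   `t`, `p`, `df`, `k`, `n`.
#' @export
escalation_test <- function(consumption, k = 4) {
  by_animal <- split(consumption, consumption$animal_id)
  rows <- lapply(by_animal, function(d) {
    d <- d[order(d$session), , drop = FALSE]
    if (nrow(d) < 2 * k) return(NULL)
    first <- mean(d$intake[seq_len(k)])
    last <- mean(d$intake[seq.int(nrow(d) - k + 1, nrow(d))])
    data.frame(animal_id = d$animal_id[1], first = first, last = last,
               pct_change = if (first > 0) 100 * (last - first) / first else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_animal <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(per_animal) || nrow(per_animal) < 3)
    stop("need >= 3 animals with complete first and last windows")
  diffs <- per_animal$last - per_animal$first
  n <- length(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  # constant differences (up to rounding) make the paired t degenerate
  if (se <= 1e-10 * max(abs(mean(diffs)), 1)) {
    tstat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    p <- if (mean(diffs) == 0) 1 else 0
  } else {
    tstat <- mean(diffs) / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  mean_first <- mean(per_animal$first)
  mean_last <- mean(per_animal$last)
  structure(list(per_animal = per_animal,
                 percent_increase = 100 * (mean_last - mean_first) / mean_first,
                 t = tstat, p = p, df = n - 1, k = k, n = n),
            class = "escalation_result")
}

#' Two-sample comparison of intake over a session window
#'
#' Student's (pooled-variance) t-test on per-animal mean intake over the
#' last `window` sessions of each group's series.
#'
#' @param cons_a,cons_b [consumption_table()]s for the two groups; animal
#'   IDs must not overlap.
#' @param window number of trailing sessions (default 10).
#' @return list: per-group window means (`mean_a`, `mean_b`), `t`, `p`,
#'   `df`, `n_a`, `n_b`.
#' @export
window_group_compare <- function(cons_a, cons_b, window = 10) {
  shared <- intersect(unique(cons_a$animal_id), unique(cons_b$animal_id))
  if (length(shared))
    stop("animal IDs present in both groups: ", paste(shared, collapse = ", "))
  window_means <- function(cons) {
    vapply(split(cons, cons$animal_id), function(d) {
      d <- d[order(d$session), , drop = FALSE]
      idx <- seq.int(max(1, nrow(d) - window + 1), nrow(d))
      mean(d$intake[idx])
    }, numeric(1))
  }
  a <- window_means(cons_a)
  b <- window_means(cons_b)
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 animals per group")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(mean_a = mean(a), mean_b = mean(b), t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter),
       n_a = length(a), n_b = length(b))
}
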