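# Fixtures are built in code at test time; nothing is read from disk
# except files the tests themselves write to tempdir().

toy_design <- function(sample_ids, n_treated, study = "A", tissue = "PFC") {
  data.frame(sample_id = sample_ids,
             group = rep(c("treated", "control"),
                         c(n_treated, length(sample_ids) - n_treated)),
             tissue = tissue, study = study, animal_id = sample_ids,
             stringsAsFactors = FALSE)
}

toy_study <- function(n_probes = 20, n1 = 5, n2 = 5, seed = 1, sd = 0.3,
                      scale = "vst", effect = 0, n_effect = 0) {
  set.seed(seed)
  base <- rnorm(n_probes, 8, 1)
  X <- matrix(rnorm(n_probes * (n1 + n2), base, sd), nrow = n_probes,
              dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n1 + n2))))
  if (n_effect > 0)
    X[seq_len(n_effect), seq_len(n1)] <- X[seq_len(n_effect), seq_len(n1)] + effect
  expression_study(X, toy_design(colnames(X), n1), scale = scale)
}

# write a matrix as a probe-ID-first TSV, optionally with "!" comment lines
write_matrix_tsv <- function(m, path, comments = NULL) {
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], formatC(m[i, ], digits = 15, format = "g")),
          collapse = "\t"), character(1))
  writeLines(c(comments, header, body), path)
  path
}

write_design_tsv <- function(design, path) {
  write_results_tsv(design, path)
  path
}

# per-vector iterated Grubbs oracle, independent of the implementation
grubbs_oracle_flags <- function(v, crit_small = 2.21, crit_large = 2.29,
                                n_switch = 10, max_removals = 2) {
  flags <- rep(FALSE, length(v))
  active <- which(!is.na(v))
  removed <- 0
  while (removed < max_removals && length(active) >= 3) {
    x <- v[active]
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    g <- max(abs(x - mean(x))) / s
    crit <- if (length(active) >= n_switch) crit_large else crit_small
    if (g <= crit) break
    i <- active[which.max(abs(x - mean(x)))]
    flags[i] <- TRUE
    active <- setdiff(active, i)
    removed <- removed + 1
  }
  flags
}
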