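test_that("the per-gene fit matches hand and textbook computations", {
  X <- rbind(p1 = c(2, 2, 2, 1, 1, 1))
  colnames(X) <- sprintf("S%d", 1:6)
  st <- expression_study(X, toy_design(colnames(X), 3), scale = "vst")
  fit <- fit_gene_models(st)
  expect_equal(fit$beta, 1)
  expect_equal(fit$s2, 0)
  expect_identical(fit$df, 4)

  set.seed(17)
  Y <- matrix(rnorm(50 * 20, 8), 50, 20,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("S%02d", 1:20)))
  sty <- expression_study(Y, toy_design(colnames(Y), 10), scale = "vst")
  fits <- fit_gene_models(sty)
  for (i in c(1, 25, 50)) {
    tt <- t.test(Y[i, 1:10], Y[i, 11:20], var.equal = TRUE)
    expect_equal(fits$beta[i], unname(diff(rev(tt$estimate))))
    pooled <- ((9 * var(Y[i, 1:10])) + (9 * var(Y[i, 11:20]))) / 18
    expect_equal(fits$s2[i], pooled)
    expect_identical(fits$df[i], 18)
  }
})

test_that("a masked value reduces the degrees of freedom by exactly one", {
  set.seed(3)
  Y <- matrix(rnorm(10 * 12, 8), 10, 12,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("S%02d", 1:12)))
  st <- expression_study(Y, toy_design(colnames(Y), 6), scale = "vst")
  full <- fit_gene_models(st)
  st$intensities[3, 2] <- NA
  masked <- fit_gene_models(st)
  expect_identical(masked$df[3], full$df[3] - 1)
  expect_identical(masked$df[-3], full$df[-3])
})

test_that("probes with fewer than 2 available values per group are skipped with reason", {
  Y <- matrix(rnorm(4 * 6, 8), 4, 6,
              dimnames = list(paste0("p", 1:4), paste0("S", 1:6)))
  Y[2, 1:2] <- NA   # one treated value left
  st <- expression_study(Y, toy_design(colnames(Y), 3), scale = "vst")
  fit <- fit_gene_models(st)
  expect_false(fit$ok[2])
  expect_match(fit$reason[2], "fewer than 2")
  expect_true(all(fit$ok[-2]))
})

test_that("the prior recovers planted hyperparameters from the hierarchical model", {
  set.seed(42)
  d0 <- 4; s02 <- 0.05; G <- 5000; dg <- 18
  sigma2 <- d0 * s02 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, dg) / dg
  pr <- ebayes_prior(s2, rep(dg, G))
  expect_gt(pr$d0, 3); expect_lt(pr$d0, 5)
  expect_lt(abs(pr$s02 - s02) / s02, 0.15)
})

test_that("the prior matches limma's estimator on shared input", {
  skip_if_not_installed("limma")
  set.seed(23)
  s2 <- 0.1 * rchisq(800, 6) / 6
  pr <- ebayes_prior(s2, rep(10, 800))
  sv <- limma::squeezeVar(s2, df = 10)
  expect_equal(pr$d0, sv$df.prior, tolerance = 1e-8)
  expect_equal(pr$s02, sv$var.prior, tolerance = 1e-8)
})

test_that("homogeneous variances drive the prior df to infinity", {
  pr <- ebayes_prior(rep(0.25, 200), rep(18, 200))
  expect_identical(pr$d0, Inf)
  # log-moment estimator carries the Jensen correction exp(ln(d/2)-digamma(d/2))
  expect_equal(pr$s02, 0.25 * exp(log(9) - digamma(9)), tolerance = 1e-8)
})

test_that("the prior is invariant to probe permutation", {
  set.seed(6)
  s2 <- rchisq(300, 5) / 5
  df <- sample(c(16, 17, 18), 300, replace = TRUE)
  p1 <- ebayes_prior(s2, df)
  ord <- sample(300)
  p2 <- ebayes_prior(s2[ord], df[ord])
  expect_equal(p1$d0, p2$d0)
  expect_equal(p1$s02, p2$s02)
})

test_that("d0 = 0 reproduces the classical pooled t exactly", {
  st <- toy_study(n_probes = 120, n1 = 10, n2 = 10, seed = 19, sd = 0.5,
                  effect = 0.8, n_effect = 20)
  fits <- fit_gene_models(st)
  res <- moderated_t(fits, list(d0 = 0, s02 = 1))
  classic_t <- vapply(seq_len(120), function(i)
    t.test(st$intensities[i, 1:10], st$intensities[i, 11:20],
           var.equal = TRUE)$statistic, numeric(1))
  classic_p <- vapply(seq_len(120), function(i)
    t.test(st$intensities[i, 1:10], st$intensities[i, 11:20],
           var.equal = TRUE)$p.value, numeric(1))
  expect_lt(max(abs(res$t - classic_t)), 1e-12)
  expect_lt(max(abs(res$p - classic_p)), 1e-12)
})

test_that("d0 = Inf replaces every gene variance with s0^2", {
  st <- toy_study(n_probes = 60, n1 = 5, n2 = 5, seed = 20)
  fits <- fit_gene_models(st)
  res <- moderated_t(fits, list(d0 = Inf, s02 = 0.09))
  expect_true(all(res$s2_post == 0.09))
  expect_equal(res$t, fits$beta / sqrt(0.09 * (1 / 5 + 1 / 5)))
})

test_that("the whole moderated stage matches limma end to end", {
  skip_if_not_installed("limma")
  # heterogeneous per-probe variances so the prior df is finite
  set.seed(31)
  n1 <- 8; n2 <- 8; p <- 300
  sds <- sqrt(0.05 * rchisq(p, 4) / 4)
  X <- matrix(rnorm(p * (n1 + n2), 8, sds), p,
              dimnames = list(sprintf("p%03d", 1:p),
                              sprintf("S%02d", 1:(n1 + n2))))
  X[1:30, 1:n1] <- X[1:30, 1:n1] + 1
  st <- expression_study(X, toy_design(colnames(X), n1), scale = "vst")
  fits <- fit_gene_models(st)
  prior <- ebayes_prior(fits$s2, fits$df)
  res <- moderated_t(fits, prior)
  design <- cbind(intercept = 1, treated = rep(c(1, 0), each = 8))
  lf <- limma::eBayes(limma::lmFit(st$intensities, design))
  expect_true(is.finite(prior$d0))
  expect_equal(prior$d0, lf$df.prior, tolerance = 1e-6)
  expect_lt(max(abs(res$t - lf$t[, "treated"])), 1e-8)
  expect_lt(max(abs(res$p - lf$p.value[, "treated"])), 1e-8)
})

test_that("p-values are monotone decreasing in |t|", {
  st <- toy_study(n_probes = 200, n1 = 6, n2 = 6, seed = 8)
  res <- moderated_t(fit_gene_models(st), list(d0 = 5, s02 = 0.1))
  ord <- order(abs(res$t))
  expect_true(all(diff(res$p[ord]) <= 1e-12))
})

test_that("signed fold changes follow the log2 convention", {
  expect_equal(fold_change(1), 2)
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(-1), -2)
  expect_equal(fold_change(-0.263), -1.2, tolerance = 1e-3)
  expect_true(all(abs(fold_change(rnorm(100))) >= 1))
})

test_that("DE calling applies strict thresholds and exact percentages", {
  tab <- data.frame(probe_id = paste0("p", 1:4),
                    beta = c(1, 0.25, 1, 0.1),
                    p = c(0.04, 0.05, 0.001, 0.01),
                    ok = TRUE)
  tab$fold_change <- fold_change(tab$beta)
  res <- call_de(tab, p_thresh = 0.05)
  expect_identical(res$table$de, c(TRUE, FALSE, TRUE, TRUE))

  res_fc <- call_de(tab, p_thresh = 0.05, fc_thresh = 1.2)
  # p4 has FC 2^0.1 = 1.07 < 1.2 despite p = 0.01
  expect_identical(res_fc$table$de, c(TRUE, FALSE, TRUE, FALSE))

  # Printed-universe identities
  mk <- function(universe, n_de) {
    d <- data.frame(probe_id = paste0("p", seq_len(universe)),
                    beta = 1, p = 0.5, ok = TRUE)
    d$p[seq_len(n_de)] <- 0.001
    d$fold_change <- fold_change(d$beta)
    call_de(d)$summary
  }
  s <- mk(12125, 531)
  expect_identical(s$pct_label, "4.4%")
  expect_equal(s$pct_de, 100 * 531 / 12125)
})

test_that("null moderated p-values are uniform on simulated data", {
  cfg <- simulation_config(n_probes = 2000, de_fraction = 0,
                           corr_fraction = 0, outlier_rate = 0,
                           detect_fail_rate = 0, seed = 29)
  sim <- simulate_study(cfg)
  pre <- preprocess_study(sim$study)
  res <- de_analyze(pre$study)
  expect_gt(ks.test(res$table$p, "punif")$p.value, 0.01)
})
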