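test_that("detection filter uses strict >80% and matches a loop oracle", {
  n <- 40L
  set.seed(11)
  X <- matrix(rexp(n * 10, 0.01), n, 10,
              dimnames = list(sprintf("p%02d", 1:n), sprintf("S%02d", 1:10)))
  D <- matrix(runif(n * 10, 0, 0.2), n, 10, dimnames = dimnames(X))
  D[1, ] <- c(rep(0.01, 8), 0.5, 0.5)   # detected on exactly 8/10 = 0.8
  D[2, ] <- 0.01                        # detected everywhere
  st <- expression_study(X, toy_design(colnames(X), 5), detection_p = D)
  filt <- detection_filter(st)
  expect_false("p01" %in% rownames(filt$intensities))
  expect_true("p02" %in% rownames(filt$intensities))

  # brute-force oracle over every probe
  keep_oracle <- vapply(seq_len(n), function(i) {
    hits <- 0
    for (j in 1:10) if (D[i, j] <= 0.05) hits <- hits + 1
    hits / 10 > 0.8
  }, logical(1))
  expect_identical(rownames(filt$intensities), rownames(X)[keep_oracle])

  all_det <- st
  all_det$detection_p[] <- 0.01
  expect_identical(nrow(detection_filter(all_det)$intensities), n)

  none <- st
  none$detection_p[] <- 0.9
  expect_error(detection_filter(none), "empty universe")
})

test_that("detection filter is idempotent", {
  sim <- simulate_study(simulation_config(n_probes = 300, seed = 2))
  once <- detection_filter(sim$study)
  twice <- detection_filter(once)
  expect_identical(once$intensities, twice$intensities)
})

test_that("the variance-model fit recovers planted coefficients", {
  cfg <- simulation_config(n_probes = 5000, var_coef = c(0, 0, 0.04),
                           de_fraction = 0, corr_fraction = 0,
                           outlier_rate = 0, detect_fail_rate = 0, seed = 3)
  sim <- simulate_study(cfg)
  params <- fit_vst(sim$study)
  expect_false(params$fallback)
  expect_lt(abs(params$c3 - 0.04) / 0.04, 0.2)
})

test_that("constant-variance data flags the fallback", {
  set.seed(8)
  mu <- 2^rnorm(500, 8, 1.5)
  X <- matrix(pmax(rnorm(500 * 10, mu, 5), 0), 500, 10,
              dimnames = list(sprintf("p%03d", 1:500), sprintf("S%02d", 1:10)))
  st <- expression_study(X, toy_design(colnames(X), 5))
  params <- fit_vst(st)
  expect_true(params$fallback)
  vst <- apply_vst(st, params)
  expect_identical(vst$scale, "vst")
  expect_equal(vst$intensities, log2(X + 1))
})

test_that("the fit is invariant to probe order", {
  sim <- simulate_study(simulation_config(n_probes = 400, seed = 6))
  p1 <- fit_vst(sim$study)
  shuffled <- sim$study
  set.seed(1)
  ord <- sample(nrow(shuffled$intensities))
  shuffled$intensities <- shuffled$intensities[ord, ]
  shuffled$detection_p <- shuffled$detection_p[ord, ]
  p2 <- fit_vst(shuffled)
  expect_equal(p1$c3, p2$c3)
  expect_equal(p1$c1, p2$c1)
})

test_that("closed-form transform equals numeric quadrature of 1/sigma", {
  for (cc in list(c(0, 0, 1), c(0, 0, 0.04), c(100, 2, 0.05))) {
    x0 <- 5
    xs <- c(8, 20, 120, 1500, 30000)
    h <- vst_transform(xs, cc[1], cc[2], cc[3]) -
      vst_transform(x0, cc[1], cc[2], cc[3])
    quad <- vapply(xs, function(xx)
      integrate(function(u) 1 / sqrt(cc[1] + cc[2] * u + cc[3] * u^2),
                x0, xx, rel.tol = 1e-12)$value, numeric(1))
    expect_equal(h, quad, tolerance = 1e-6)
  }
})

test_that("the transform is strictly monotone and rank-preserving", {
  sim <- simulate_study(simulation_config(n_probes = 200, seed = 12))
  params <- fit_vst(sim$study)
  vst <- apply_vst(sim$study, params)
  for (i in c(1, 50, 200)) {
    expect_identical(order(vst$intensities[i, ]),
                     order(sim$study$intensities[i, ]))
  }
  xs <- sort(runif(100, 1, 1e5))
  hs <- vst_transform(xs, params$c1, params$c2, params$c3)
  expect_true(all(diff(hs) > 0))
})

test_that("the transform stabilizes the planted quadratic variance", {
  cfg <- simulation_config(n_probes = 3000, var_coef = c(0, 0, 0.04),
                           de_fraction = 0, corr_fraction = 0,
                           outlier_rate = 0, detect_fail_rate = 0, seed = 3)
  sim <- simulate_study(cfg)
  v_raw <- apply(sim$study$intensities, 1, var)
  ratio_raw <- quantile(v_raw, 0.9) / quantile(v_raw, 0.1)
  vst <- apply_vst(sim$study, fit_vst(sim$study))
  v_vst <- apply(vst$intensities, 1, var)
  ratio_vst <- quantile(v_vst, 0.9) / quantile(v_vst, 0.1)
  expect_gte(ratio_raw, 10)
  expect_lt(ratio_vst, 3)
})

test_that("quantile normalization matches its closed form and oracle", {
  X <- cbind(S1 = c(1, 2, 3), S2 = c(3, 4, 5))
  rownames(X) <- paste0("p", 1:3)
  st <- expression_study(X, toy_design(colnames(X), 1), scale = "vst")
  qn <- suppressWarnings(quantile_normalize(st))
  expect_equal(unname(qn$intensities), cbind(c(2, 3, 4), c(2, 3, 4)))
  expect_identical(qn$scale, "vst_quantile")

  set.seed(4)
  Y <- matrix(rnorm(300), 50, 6,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("S%d", 1:6)))
  sty <- expression_study(Y, toy_design(colnames(Y), 3), scale = "vst")
  qy <- quantile_normalize(sty)$intensities
  # independent sort/average/unsort oracle
  ref <- rowMeans(apply(Y, 2, sort))
  oracle <- Y
  for (j in 1:6) oracle[, j] <- ref[rank(Y[, j])]
  expect_equal(qy, oracle)
  # all column distributions identical
  sorted <- apply(qy, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) == 0))
})

test_that("quantile normalization is idempotent and sample-permutation equivariant", {
  set.seed(9)
  Y <- matrix(rnorm(200, 8), 40, 5,
              dimnames = list(sprintf("p%02d", 1:40), sprintf("S%d", 1:5)))
  st <- expression_study(Y, toy_design(colnames(Y), 2), scale = "vst")
  q1 <- quantile_normalize(st)
  q2 <- quantile_normalize(q1)
  expect_equal(q1$intensities, q2$intensities)
  perm <- c(3, 1, 5, 2, 4)
  stp <- st
  stp$intensities <- st$intensities[, perm]
  stp$design <- st$design[perm, ]
  qp <- quantile_normalize(stp)
  expect_equal(qp$intensities, q1$intensities[, perm])
})

test_that("ties receive the mean of the reference values at tied ranks", {
  X <- cbind(S1 = c(1, 1, 5), S2 = c(10, 20, 30))
  rownames(X) <- paste0("p", 1:3)
  st <- expression_study(X, toy_design(colnames(X), 1), scale = "vst")
  qn <- quantile_normalize(st)$intensities
  ref <- rowMeans(cbind(sort(X[, 1]), sort(X[, 2])))
  expect_equal(unname(qn[, 1]),
               unname(c(mean(ref[1:2]), mean(ref[1:2]), ref[3])))
})

test_that("Grubbs screening matches the brute-force oracle and flags the gross value", {
  v <- c(1, 1.1, 0.9, 1.05, 0.95, 1.02, 0.98, 1.03, 0.97, 10)
  X <- rbind(p1 = v)
  colnames(X) <- sprintf("S%02d", 1:10)
  st <- expression_study(X, toy_design(colnames(X), 0)[, ], scale = "vst")
  st$design$group <- "control"
  mask <- grubbs_screen(st)
  g <- max(abs(v - mean(v))) / sd(v)
  expect_gt(g, 2.29)
  expect_identical(which(mask$mask[1, ]), c(S10 = 10L))
})

test_that("zero-variance vectors are never flagged", {
  X <- rbind(p1 = rep(5, 10))
  colnames(X) <- sprintf("S%02d", 1:10)
  st <- expression_study(X, toy_design(colnames(X), 5), scale = "vst")
  expect_false(any(grubbs_screen(st)$mask))
})

test_that("the critical value switches between 2.21 (n=9) and 2.29 (n=10)", {
  # build a vector whose Grubbs statistic lies strictly between the criticals
  set.seed(14)
  base <- rnorm(8)
  make_v <- function(a) c(base, a)
  g_of <- function(a) {
    v <- make_v(a)
    max(abs(v - mean(v))) / sd(v)
  }
  a <- uniroot(function(a) g_of(a) - 2.25, c(2, 50))$root
  v9 <- make_v(a)
  expect_gt(g_of(a), 2.21); expect_lt(g_of(a), 2.29)

  m9 <- rbind(p1 = v9)
  colnames(m9) <- sprintf("S%02d", 1:9)
  st9 <- expression_study(m9, toy_design(colnames(m9), 9), scale = "vst")
  expect_true(any(grubbs_screen(st9)$mask))

  # pad to n = 10 keeping G in the gap: recompute with one extra midpoint
  g10_of <- function(a) {
    v <- c(base, mean(base), a)
    max(abs(v - mean(v))) / sd(v)
  }
  a10 <- uniroot(function(a) g10_of(a) - 2.25, c(2, 50))$root
  m10 <- rbind(p1 = c(base, mean(base), a10))
  colnames(m10) <- sprintf("S%02d", 1:10)
  st10 <- expression_study(m10, toy_design(colnames(m10), 10), scale = "vst")
  expect_false(any(grubbs_screen(st10)$mask))
})

test_that("iterated screening removes at most two values per probe/group", {
  v <- c(rnorm(8, 0, 0.1), 50, 60, 70)
  X <- rbind(p1 = v)
  colnames(X) <- sprintf("S%02d", 1:11)
  st <- expression_study(X, toy_design(colnames(X), 11), scale = "vst")
  mask <- grubbs_screen(st)
  expect_lte(sum(mask$mask), 2)
})

test_that("random matrices agree with the per-vector oracle", {
  set.seed(21)
  n <- 200
  X <- matrix(rnorm(n * 20, 8, 0.5), n, 20,
              dimnames = list(sprintf("p%03d", 1:n), sprintf("S%02d", 1:20)))
  X[cbind(sample(n, 10), sample(20, 10, replace = TRUE))] <- 20
  st <- expression_study(X, toy_design(colnames(X), 10), scale = "vst")
  mask <- grubbs_screen(st)
  oracle <- t(vapply(seq_len(n), function(i)
    c(grubbs_oracle_flags(X[i, 1:10]), grubbs_oracle_flags(X[i, 11:20])),
    logical(20)))
  expect_identical(unname(mask$mask), oracle)
})

test_that("sample flagging is strict and recovers the planted degenerate sample", {
  mask <- structure(list(
    mask = matrix(FALSE, 100, 2, dimnames = list(NULL, c("A", "B"))),
    sample_fraction = c(A = 0.06, B = 0.05)), class = "outlier_mask")
  expect_identical(flag_outlier_samples(mask), "A")

  sim <- simulate_study(simulation_config(n_probes = 800, seed = 7,
                                          degenerate_sample = TRUE))
  pre <- preprocess_study(sim$study)
  expect_identical(pre$removed_samples, sim$truth$degenerate_sample)
})

test_that("the composed chain only changes shape via filter rows and removed columns", {
  sim <- simulate_study(simulation_config(n_probes = 500, seed = 10))
  pre <- preprocess_study(sim$study)
  filt <- detection_filter(sim$study)
  expect_identical(nrow(pre$study$intensities), nrow(filt$intensities))
  expect_identical(ncol(pre$study$intensities),
                   ncol(sim$study$intensities) - length(pre$removed_samples))
})
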