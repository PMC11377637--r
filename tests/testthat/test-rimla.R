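test_that("per-lesion COV follows the sample-statistic definition", {
  q <- rbind(c(10, 10, 10, 10), c(8, 10, 10, 12))
  res <- compute_cov(q)
  expect_equal(unname(res$cov[1]), 0)
  expect_equal(unname(res$cov[2]), sqrt(8 / 3) / 10, tolerance = 1e-12)
  expect_equal(res$mean_cov, mean(res$cov))
  expect_error(compute_cov(matrix(1:3, ncol = 1)))
})

test_that("mean COV estimator is consistent for the generating COV", {
  cfg <- synth_config(cov_true = 0.17)
  sr <- gen_scan_rescan(cfg, 500, seed = 31)
  est <- compute_cov(sr)$mean_cov
  expect_lt(abs(est - 0.17) / 0.17, 0.15)
})

test_that("scan-rescan matching follows overlap with lower-id tie-break", {
  base <- array(0L, c(12, 6, 6))
  base[2:3, 2:3, 2:3] <- 1L
  base[8:9, 2:3, 2:3] <- 2L
  lm1 <- new_lesion_label_map(base, c(1, 1, 1))
  # identical maps: identity matching
  m <- match_scan_rescan(list(lm1, lm1, lm1, lm1))
  expect_equal(dim(m), c(2L, 4L))
  expect_true(all(m == m[, 1]))
  # lesion 2 absent in scan 3: dropped
  miss <- base; miss[miss == 2L] <- 0L
  m2 <- match_scan_rescan(list(lm1, lm1, new_lesion_label_map(miss, c(1, 1, 1))))
  expect_identical(rownames(m2), "1")
  # equal-overlap tie resolves to the lower label id
  tie <- array(0L, c(12, 6, 6))
  tie[2, 2:3, 2:3] <- 3L
  tie[3, 2:3, 2:3] <- 1L
  lm_tie <- new_lesion_label_map(tie, c(1, 1, 1))
  ref <- array(0L, c(12, 6, 6)); ref[2:3, 2:3, 2:3] <- 1L
  m3 <- match_scan_rescan(list(new_lesion_label_map(ref, c(1, 1, 1)), lm_tie))
  expect_equal(unname(m3["1", 2]), 4)      # volume of label 1, the lower id
  expect_error(match_scan_rescan(list(lm1)), "2 scans")
})

test_that("matching drops lesions outside the volume window", {
  big <- array(0L, c(20, 20, 20))
  big[2:13, 2:13, 2:3] <- 1L                     # 288 uL, above 150
  big[16, 16, 16] <- 2L                          # 1 uL, below 3
  big[16:17, 2:3, 2:3] <- 3L                     # 8 uL, inside
  lm <- new_lesion_label_map(big, c(1, 1, 1))
  m <- match_scan_rescan(list(lm, lm))
  expect_identical(rownames(m), "3")
})

test_that("synthetic draws honour the COV noise model", {
  v <- c(10, 12, NA, 16)
  d0 <- simulate_volumes(v, cov = 0, n_synth = 50, seed = 1)
  expect_equal(ncol(d0), 3)                       # undetected: no draws
  expect_true(all(d0[, 1] == 10) && all(d0[, 3] == 16))
  d <- simulate_volumes(c(10, 20), cov = 0.17, n_synth = 100, seed = 2)
  expect_true(all(d > 0))
  for (j in 1:2) {
    mu <- c(10, 20)[j]
    expect_lt(abs(mean(d[, j]) - mu), 3 * 0.17 * mu / sqrt(100))
  }
})

test_that("bootstrap slopes reduce to OLS in the noise-free case and scale with time units", {
  times <- c(0, 180, 360, 540)
  v <- 5 + 0.02 * times
  draws <- simulate_volumes(v, cov = 0, n_synth = 100, seed = 3)
  s <- bootstrap_slopes(draws, times, n_boot = 100, seed = 3)
  expect_true(all(abs(s - 0.02) < 1e-12))
  s_yr <- bootstrap_slopes(draws, times / 365.25, n_boot = 100, seed = 3)
  expect_equal(as.vector(s_yr), as.vector(s) * 365.25, tolerance = 1e-9)
  expect_error(bootstrap_slopes(draws[, 1, drop = FALSE], times[1]), "slope undefined")
})

test_that("null slopes centre on zero within Monte Carlo error", {
  draws <- simulate_volumes(rep(20, 4), cov = 0.2, n_synth = 100, seed = 4)
  s <- bootstrap_slopes(draws, c(0, 180, 360, 540), n_boot = 500, seed = 4)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s)), 3 * se + 1e-12)
})

test_that("the sign-fraction rule is inclusive at 95 percent", {
  mk <- function(npos, n = 100) {
    s <- c(rep(0.1, npos), rep(-0.1, n - npos))
    attr(s, "intercepts") <- rep(5, n)
    s
  }
  det <- rep(TRUE, 4)
  f100 <- classify_lesion(mk(100), det)
  expect_identical(f100$label, "enlarging")
  expect_equal(f100$bootstrap_p, 0)
  expect_identical(classify_lesion(mk(95), det)$label, "enlarging")
  expect_identical(classify_lesion(mk(94), det)$label, "stable")
  expect_identical(classify_lesion(mk(5), det)$label, "shrinking")
  expect_equal(classify_lesion(mk(94), det)$bootstrap_p, 0.06)
  fnew <- classify_lesion(NULL, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(fnew$label, "new")
  expect_true(is.na(fnew$median_slope))
  expect_identical(classify_lesion(NULL, c(TRUE, FALSE, TRUE, TRUE))$label,
                   "discarded")
})

test_that("rimla fits are invariant to row order and volume scale", {
  cfg <- synth_config(seed = 5)
  ser <- gen_lesion_series(cfg, 12, seed = 5)
  fit <- rimla(ser, cov = 0.17, seed = 9)
  # permuted row order
  perm <- ser[sample(nrow(ser)), ]
  fit_p <- rimla(perm, cov = 0.17, seed = 9)
  expect_equal(fit$fits, fit_p$fits)
  # volume rescaling: labels unchanged, slopes scale
  ser2 <- ser; ser2$volume_uL <- ser2$volume_uL * 3
  fit_s <- rimla(ser2, cov = 0.17, seed = 9)
  expect_identical(fit$fits$label, fit_s$fits$label)
  expect_equal(fit_s$fits$median_slope, fit$fits$median_slope * 3,
               tolerance = 1e-9)
})

test_that("rimla recovers strong planted slopes and handles empty input", {
  cfg <- synth_config(seed = 6)
  ser <- gen_lesion_series(cfg, 60,
                           classes = rep(c("enlarging", "shrinking", "stable", "new"),
                                         15), seed = 6)
  fit <- rimla(ser, cov = 0.17, seed = 7)
  truth <- attr(ser, "truth")
  agree <- mean(fit$fits$label ==
                  truth$class[match(fit$fits$lesion_id, truth$lesion_id)])
  expect_gt(agree, 0.85)
  expect_identical(sort(unique(fit$fits$label)),
                   sort(unique(truth$class)))
  empty <- ser[0, ]
  fit0 <- rimla(empty, cov = 0.17)
  expect_equal(nrow(fit0$fits), 0)
})

test_that("rimla accessors expose slopes and summaries", {
  cfg <- synth_config(seed = 8)
  ser <- gen_lesion_series(cfg, 6, classes = rep("enlarging", 6), seed = 8)
  fit <- rimla(ser, cov = 0.1, seed = 8)
  co <- coef(fit)
  expect_length(co, 6)
  expect_true(all(co > 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.rimla")
  expect_output(print(fit), "RIMLA")
})
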