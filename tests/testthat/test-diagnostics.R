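test_that("variance explained sums 2p(1-p)beta^2 over independent SNPs", {
  one <- data.frame(rsid = "rs1", eaf = 0.5, beta = 0.1)
  expect_equal(variance_explained(one), 0.005)

  a <- data.frame(rsid = "a", eaf = 0.3, beta = 0.05)
  b <- data.frame(rsid = "b", eaf = 0.1, beta = -0.02)
  expect_equal(variance_explained(rbind(a, b)),
               variance_explained(a) + variance_explained(b))

  zero <- data.frame(rsid = "z", eaf = 0.2, beta = 0)
  expect_equal(variance_explained(rbind(a, zero)), variance_explained(a))

  miss <- data.frame(rsid = c("a", "b"), eaf = c(0.3, NA), beta = c(0.1, 0.1))
  expect_error(variance_explained(miss), "missing for: b")
})

test_that("F-statistic follows its formula and monotonicities", {
  # formula oracle: (r2/(1-r2)) * ((n-k-1)/k)
  expect_equal(f_statistic(0.0071, 61079, 5), 87.3438, tolerance = 1e-4)
  expect_equal(f_statistic(0.0071, 39400, 5), 56.3395, tolerance = 1e-4)
  expect_equal(f_statistic(0, 1000, 5), 0)

  expect_gt(f_statistic(0.01, 61079, 5), f_statistic(0.0071, 61079, 5))
  expect_gt(f_statistic(0.0071, 70000, 5), f_statistic(0.0071, 61079, 5))
  expect_lt(f_statistic(0.0071, 61079, 6), f_statistic(0.0071, 61079, 5))
  expect_error(f_statistic(1.2, 1000, 5), "r2")
  expect_error(f_statistic(0.01, 5, 5), "exceed")
})

test_that("I2GX hits its limits and is scale-invariant", {
  spread <- data.frame(beta_exposure = c(0.02, 0.08, 0.20),
                       se_exposure = rep(1e-7, 3),
                       se_outcome = rep(0.1, 3))
  expect_gt(i2_gx(spread), 0.999999)

  flat <- data.frame(beta_exposure = rep(0.05, 4),
                     se_exposure = rep(0.01, 4), se_outcome = rep(0.1, 4))
  expect_equal(i2_gx(flat), 0)

  set.seed(19)
  dat <- data.frame(beta_exposure = runif(10, 0.02, 0.1),
                    se_exposure = runif(10, 0.005, 0.02),
                    se_outcome = runif(10, 0.05, 0.1))
  for (weighting in c("egger", "exposure")) {
    v <- i2_gx(dat, weighting)
    expect_true(v >= 0 && v < 1)
    scaled <- dat
    scaled$beta_exposure <- 3.7 * scaled$beta_exposure
    scaled$se_exposure <- 3.7 * scaled$se_exposure
    expect_equal(i2_gx(scaled, weighting), v, tolerance = 1e-12)
  }
})

test_that("I2GX matches its Q expectation under simulation", {
  # exposure-weighted Q_GX has expectation (L-1) + sum v_j (g_j - g_bar)^2
  set.seed(23)
  L <- 12
  gamma <- runif(L, 0.02, 0.08)
  sx <- rep(0.01, L)
  v <- 1 / sx^2
  gbar <- sum(v * gamma) / sum(v)
  expect_q <- (L - 1) + sum(v * (gamma - gbar)^2)
  reps <- 400
  qs <- vapply(seq_len(reps), function(i) {
    bx <- rnorm(L, gamma, sx)
    mu <- sum(v * bx) / sum(v)
    sum(v * (bx - mu)^2)
  }, numeric(1))
  mc_se <- sd(qs) / sqrt(reps)
  expect_lt(abs(mean(qs) - expect_q), 4 * mc_se)
  # and the implied I2GX level is reproduced by the estimator
  dat <- data.frame(beta_exposure = rnorm(L, gamma, sx), se_exposure = sx,
                    se_outcome = 0.1)
  expect_equal(i2_gx(dat, "exposure"),
               max(0, (mean(qs) - (L - 1)) / mean(qs)), tolerance = 0.15)
})

test_that("power calculation: null level, frozen value, monotonicity", {
  # under the null the two-sided rejection probability is exactly alpha
  expect_equal(power_binary_outcome(1e5, 0.5, 0.01, 1, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  # frozen numeric oracle at the case-study face-value inputs
  expect_equal(power_binary_outcome(72729, 44825 / 72729, 0.0071, 1.25),
               0.6935, tolerance = 1e-4)
  # strictly increasing in n, r2 and |log OR|
  base <- power_binary_outcome(5e4, 0.5, 0.005, 1.2)
  expect_gt(power_binary_outcome(6e4, 0.5, 0.005, 1.2), base)
  expect_gt(power_binary_outcome(5e4, 0.5, 0.006, 1.2), base)
  expect_gt(power_binary_outcome(5e4, 0.5, 0.005, 1.3), base)
  expect_equal(power_binary_outcome(5e4, 0.5, 0.005, 1 / 1.2),
               base, tolerance = 1e-12)
})

test_that("detectable OR inverts the power formula and round-trips", {
  for (target in c(0.5, 0.8, 0.9)) {
    sol <- detectable_or(72729, 44825 / 72729, 0.0071, target)
    expect_gt(sol$or, 1)
    expect_equal(sol$or_protective, 1 / sol$or, tolerance = 1e-12)
    expect_equal(power_binary_outcome(72729, 44825 / 72729, 0.0071, sol$or),
                 target, tolerance = 1e-4)
  }
  expect_error(detectable_or(1e4, 0.5, 0.01, target_power = 0.04),
               "no solution")
})

test_that("Bonferroni screen thresholds and flags behave as specified", {
  lk <- calcium_lookup_table()
  res <- bonferroni_screen(lk$lookups, lk$n_lookups, alpha = 0.05)
  thr <- setNames(res$thresholds$threshold, res$thresholds$rsid)
  expect_equal(unname(thr["rs1550532"]), 5.8e-5, tolerance = 0.01)
  expect_equal(unname(thr["rs780094"]), 4.7e-5, tolerance = 0.01)
  expect_setequal(res$flagged, c("rs780094", "rs1550532"))

  # a cross-trait p of 1e-3 at threshold 5.8e-5 is not flagged
  mild <- data.frame(rsid = "rs9", trait = "ldl", pvalue = 1e-3)
  expect_length(bonferroni_screen(mild, c(rs9 = 859))$flagged, 0)

  # smaller alpha never flags more SNPs
  prev <- NULL
  for (alpha in c(0.05, 0.01, 0.001, 1e-4)) {
    fl <- bonferroni_screen(lk$lookups, lk$n_lookups, alpha = alpha)$flagged
    if (!is.null(prev)) expect_true(all(fl %in% prev))
    prev <- fl
  }

  expect_error(bonferroni_screen(mild, c(other = 10)), "no look-up count")
})
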