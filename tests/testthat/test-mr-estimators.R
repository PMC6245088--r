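test_that("Wald ratios follow the delta-method formulas", {
  snp <- data.frame(rsid = "rs1", beta_exposure = 0.1, se_exposure = 0.01,
                    beta_outcome = 0.02, se_outcome = 0.01)
  r1 <- wald_ratio(snp, order = "first")
  expect_equal(r1$beta, 0.2)
  expect_equal(r1$se, 0.1)
  expect_equal(r1$weight, 100)

  snp$se_exposure <- 0.05
  r2 <- wald_ratio(snp, order = "second")
  expect_equal(r2$se, sqrt(0.01 + 0.01), tolerance = 1e-12)  # 0.1414

  snp$beta_outcome <- 0
  expect_equal(wald_ratio(snp)$beta, 0)
  expect_equal(wald_ratio(snp)$se, 0.01 / 0.1)

  snp$beta_exposure <- 0
  expect_error(wald_ratio(snp), "undefined.*rs1")
})

test_that("IVW matches its closed form and the fixed-effect meta-analysis oracle", {
  ratios <- random_ratios(8, seed = 3)
  res <- mr_ivw(ratios, effects_model = "fixed")
  skip_if_not_installed("metafor")
  oracle <- metafor::rma(yi = ratios$beta, sei = ratios$se, method = "FE")
  expect_equal(res$beta, as.numeric(oracle$beta), tolerance = 1e-10)
  expect_equal(res$se, oracle$se, tolerance = 1e-10)
  het <- mr_heterogeneity(ratios)
  expect_equal(het$q, oracle$QE, tolerance = 1e-10)
  expect_equal(het$pvalue, oracle$QEp, tolerance = 1e-10)
})

test_that("IVW degenerate and equal-weight cases behave as stated", {
  one <- data.frame(rsid = "rs1", beta = 0.2, se = 0.1)
  res <- mr_ivw(one)
  expect_equal(res$beta, 0.2)
  expect_equal(res$se, 0.1)
  expect_equal(res$df, 0)
  expect_true(is.na(res$pvalue))

  two <- data.frame(rsid = c("a", "b"), beta = c(0.3, 0.3), se = c(0.1, 0.1))
  res2 <- mr_ivw(two, effects_model = "fixed")
  expect_equal(res2$beta, 0.3)
  expect_equal(res2$se, 0.1 / sqrt(2), tolerance = 1e-12)
})

test_that("IVW is invariant to SNP order and joint sign flips", {
  set.seed(21)
  for (rep in 1:5) {
    dat <- random_harmonized(6, theta = 0.2, seed = rep)
    base <- mr_ivw(dat, effects_model = "fixed")
    perm <- mr_ivw(dat[sample(nrow(dat)), ], effects_model = "fixed")
    expect_equal(perm$beta, base$beta, tolerance = 1e-12)
    flip <- dat
    i <- sample(nrow(dat), 2)
    flip$beta_exposure[i] <- -flip$beta_exposure[i]
    flip$beta_outcome[i] <- -flip$beta_outcome[i]
    expect_equal(mr_ivw(flip, effects_model = "fixed")$beta, base$beta,
                 tolerance = 1e-12)
  }
})

test_that("maximum likelihood equals IVW in the vanishing exposure-noise limit", {
  dat <- random_harmonized(10, theta = 0.25, seed = 5)
  dat$se_exposure <- 1e-8
  ml <- mr_max_likelihood(dat, effects_model = "fixed")
  ivw <- mr_ivw(dat, effects_model = "fixed")
  expect_equal(ml$beta, ivw$beta, tolerance = 1e-6)
  expect_equal(ml$se, ivw$se, tolerance = 1e-6)
  expect_true(attr(ml, "convergence")$converged)

  # exactly-known exposure effects take the closed IVW form
  dat$se_exposure <- 0
  ml0 <- mr_max_likelihood(dat, effects_model = "fixed")
  expect_equal(ml0$beta, ivw$beta, tolerance = 1e-10)
})

test_that("maximum likelihood agrees with a direct full-likelihood maximizer", {
  dat <- random_harmonized(5, theta = 0.3, seed = 9, sx = 0.05, sy = 0.05)
  ml <- mr_max_likelihood(dat, effects_model = "fixed")
  negll <- function(par) {
    theta <- par[1]; gamma <- par[-1]
    -sum(dnorm(dat$beta_exposure, gamma, dat$se_exposure, log = TRUE)) -
      sum(dnorm(dat$beta_outcome, theta * gamma, dat$se_outcome, log = TRUE))
  }
  opt <- optim(c(0, dat$beta_exposure), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(ml$beta, opt$par[1], tolerance = 1e-5)
})

test_that("maximum likelihood recovers a simulated causal effect", {
  cfg <- simulation_config(n_snps = 50, theta = 0.3,
                           se_exposure_range = c(0.001, 0.002),
                           se_outcome_range = c(0.01, 0.02), seed = 104)
  reps <- 60
  est <- vapply(seq_len(reps), function(i) {
    cfg$seed <- 1000 + i
    mr_max_likelihood(simulate_summary_stats(cfg))$beta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.3), 3 * mc_se + 1e-4)
})

test_that("Egger regression recovers exact linear structure", {
  dat <- random_harmonized(6, theta = 0.4, seed = 2)
  theta <- 0.4; c0 <- 0.03
  dat$beta_outcome <- theta * dat$beta_exposure + c0  # noiseless
  e <- mr_egger(dat)
  expect_equal(e$slope$beta, theta, tolerance = 1e-10)
  expect_equal(e$intercept$estimate, c0, tolerance = 1e-10)

  dat$beta_outcome <- theta * dat$beta_exposure
  e0 <- mr_egger(dat)
  expect_equal(e0$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(e0$slope$beta, theta, tolerance = 1e-10)
})

test_that("Egger with the intercept constrained to zero reproduces fixed IVW", {
  for (seed in 1:4) {
    dat <- random_harmonized(7, theta = 0.2, seed = seed)
    e <- mr_egger(dat, constrain_intercept = TRUE)
    ivw <- mr_ivw(dat, effects_model = "fixed")
    expect_equal(e$slope$beta, ivw$beta, tolerance = 1e-10)
  }
})

test_that("Egger matches the weighted normal equations and scales SEs by max(1, RSE)", {
  dat <- random_harmonized(8, theta = 0.3, seed = 13, sy = 0.04)
  e <- mr_egger(dat)
  # independent oracle: solve the 2x2 weighted normal equations
  w <- 1 / dat$se_outcome^2
  X <- cbind(1, dat$beta_exposure)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * dat$beta_outcome))
  expect_equal(e$intercept$estimate, coefs[1], tolerance = 1e-10)
  expect_equal(e$slope$beta, coefs[2], tolerance = 1e-10)
  resid <- dat$beta_outcome - X %*% coefs
  rse <- sqrt(sum(w * resid^2) / (nrow(dat) - 2))
  expect_equal(e$rse, rse, tolerance = 1e-10)
  se_unit <- sqrt(diag(solve(xtwx)))
  expect_equal(c(e$intercept$se, e$slope$se),
               unname(se_unit * max(1, rse)), tolerance = 1e-10)
})

test_that("Egger rejects negative orientation and rank-deficient designs", {
  dat <- random_harmonized(5, seed = 1)
  bad <- dat; bad$beta_exposure[2] <- -bad$beta_exposure[2]
  expect_error(mr_egger(bad), "oriented non-negative")
  flat <- dat; flat$beta_exposure <- 0.1
  expect_error(mr_egger(flat), "rank-deficient")
  expect_error(mr_egger(dat[1:2, ]), "at least three")
})

test_that("weighted median interpolates the inverse-variance percentile", {
  # three equal weights: middle value
  eq <- data.frame(rsid = c("a", "b", "c"), beta = c(1, 2, 3),
                   se = rep(0.5, 3))
  expect_equal(mr_weighted_median(eq, n_boot = 100, seed = 1)$beta, 2)

  # hand-computed interpolation oracle: weights renormalize to
  # (0.7, 0.15, 0.15), positions s = (0.35, 0.775, 0.925),
  # estimate = -0.2 + (0.5-0.35)/(0.775-0.35) * (1 - (-0.2)) = 0.2235294
  se <- 1 / sqrt(c(0.7, 0.15, 0.15))
  wm <- data.frame(rsid = c("a", "b", "c"), beta = c(-0.2, 1, 2), se = se)
  expect_equal(mr_weighted_median(wm, n_boot = 100, seed = 1)$beta,
               0.2235294, tolerance = 1e-7)
})

test_that("equal-weight weighted median equals the interpolated sample median", {
  set.seed(31)
  for (L in c(5, 6, 9, 12)) {
    b <- rnorm(L)
    dat <- data.frame(rsid = sprintf("rs%02d", seq_len(L)), beta = b,
                      se = rep(0.3, L))
    expect_equal(mr_weighted_median(dat, n_boot = 100, seed = 1)$beta,
                 median(b), tolerance = 1e-12)
  }
})

test_that("weighted-median bootstrap is seeded and reproducible", {
  ratios <- random_ratios(6, seed = 8)
  a <- mr_weighted_median(ratios, n_boot = 500, seed = 42)
  b <- mr_weighted_median(ratios, n_boot = 500, seed = 42)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(ratios, n_boot = 500, seed = 43)
  expect_false(identical(a$se, c$se))
  expect_error(mr_weighted_median(ratios, n_boot = 50), "at least 100")
  # RNG state of the caller is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(mr_weighted_median(ratios, n_boot = 100, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("Cochran's Q is zero for identical ratios and translation-invariant", {
  same <- data.frame(rsid = letters[1:4], beta = rep(0.2, 4),
                     se = c(0.1, 0.2, 0.3, 0.4))
  h <- mr_heterogeneity(same)
  expect_equal(h$q, 0)
  expect_equal(h$i2, 0)
  expect_equal(h$pvalue, 1)

  ratios <- random_ratios(7, seed = 15)
  h1 <- mr_heterogeneity(ratios)
  shifted <- ratios; shifted$beta <- shifted$beta + 0.7
  expect_equal(mr_heterogeneity(shifted)$q, h1$q, tolerance = 1e-10)
  expect_true(h1$i2 >= 0 && h1$i2 < 100)
})

test_that("leave-one-out returns one labelled result per excluded SNP", {
  ratios <- random_ratios(5, seed = 4)
  loo <- mr_leave_one_out(ratios, mr_ivw, effects_model = "fixed")
  expect_equal(nrow(loo), 5)
  expect_setequal(loo$excluded, ratios$rsid)
  expect_true(all(loo$n_snps == 4))

  # excluding a numerically weightless SNP leaves the estimate unchanged
  heavy <- rbind(ratios,
                 data.frame(rsid = "rs_null", beta = 5, se = 1e8,
                            weight = 1e-16))
  full <- mr_ivw(heavy, effects_model = "fixed")
  drop_null <- mr_ivw(heavy[heavy$rsid != "rs_null", ],
                      effects_model = "fixed")
  expect_equal(full$beta, drop_null$beta, tolerance = 1e-10)

  # two SNPs: each result is the other's Wald ratio
  two <- ratios[1:2, ]
  loo2 <- mr_leave_one_out(two, mr_ivw)
  expect_equal(loo2$beta, rev(two$beta))
  expect_equal(loo2$se, rev(two$se))

  # estimator errors carry the excluded label
  expect_error(
    mr_leave_one_out(ratios[1:3, ], function(d) stop("boom")),
    "excluding rs001")
})

test_that("scale_estimate rescales beta and SE, preserving the t statistic", {
  ratios <- random_ratios(5, seed = 6)
  res <- mr_ivw(ratios, effects_model = "fixed")
  expect_equal(scale_estimate(res, 1), res)
  doubled <- scale_estimate(res, 2)
  expect_equal(doubled$beta, 2 * res$beta)
  expect_equal(doubled$se, 2 * res$se)
  expect_equal(doubled$pvalue, res$pvalue, tolerance = 1e-12)
  back <- scale_estimate(scale_estimate(res, 0.5), 2)
  expect_equal(back, res)
  expect_error(scale_estimate(res, -1), "positive")
})
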