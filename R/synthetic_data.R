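#' Configuration for synthetic two-sample summary statistics
#'
#' Defines the generative model used by [simulate_summary_stats()]:
#' true per-SNP exposure effects `gamma_j` (SD units) are drawn from
#' `gamma_dist`; a fraction `prop_invalid` of SNPs receives a horizontal
#' pleiotropy effect `alpha_j` under the chosen regime; the observed
#' summary estimates are `beta_exposure_j ~ N(gamma_j, se_exposure_j^2)`
#' and `beta_outcome_j ~ N(theta * gamma_j + alpha_j, se_outcome_j^2)`
#' with per-SNP SEs drawn uniformly from the stated ranges. Pleiotropy
#' enters the outcome only: the generator works entirely at summary
#' level, which is sufficient to exercise every estimator contract.
#'
#' The default effect-size and SE ranges give per-SNP F-statistics
#' `(gamma/se_exposure)^2` between roughly 10 and 100, straddling the
#' weak-instrument regime.
#'
#' Pleiotropy regimes: `"none"`; `"balanced"` (`alpha ~ N(0, sd)`,
#' InSIDE holds); `"directional"` (`alpha ~ N(mean, sd)`, InSIDE holds);
#' `"inside_violating"` (`alpha` correlated with instrument strength
#' `gamma` at correlation `cor`).
#'
#' @param n_snps Number of instrument SNPs L (>= 2).
#' @param theta True causal effect, log-OR per exposure SD.
#' @param gamma_dist List describing the distribution of true exposure
#'   effects: `list(dist = "uniform", min, max)` or
#'   `list(dist = "normal", mean, sd)`, in SD units per allele.
#' @param se_exposure_range,se_outcome_range Length-2 ranges (min, max)
#'   for the per-SNP standard errors.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the pleiotropy
#'   effects (log-odds per allele) for the invalid fraction.
#' @param pleiotropy_cor Correlation between pleiotropy and `gamma` for
#'   the `"inside_violating"` regime, in `[-1, 1]`.
#' @param prop_invalid Fraction of SNPs receiving pleiotropy, in `[0, 1]`.
#' @param seed RNG seed making the draw fully reproducible.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 50,
                              theta = 0,
                              gamma_dist = list(dist = "uniform",
                                                min = 0.02, max = 0.06),
                              se_exposure_range = c(0.0055, 0.0065),
                              se_outcome_range = c(0.05, 0.10),
                              pleiotropy = c("none", "balanced",
                                             "directional",
                                             "inside_violating"),
                              pleiotropy_mean = 0,
                              pleiotropy_sd = 0,
                              pleiotropy_cor = 0,
                              prop_invalid = 0,
                              seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_snps >= 2, prop_invalid >= 0, prop_invalid <= 1,
            pleiotropy_sd >= 0,
            pleiotropy_cor >= -1, pleiotropy_cor <= 1,
            length(se_exposure_range) == 2L, length(se_outcome_range) == 2L,
            all(se_exposure_range >= 0), all(se_outcome_range >= 0),
            se_exposure_range[1] <= se_exposure_range[2],
            se_outcome_range[1] <= se_outcome_range[2])
  if (!is.list(gamma_dist) || is.null(gamma_dist$dist) ||
      !gamma_dist$dist %in% c("uniform", "normal")) {
    stop("gamma_dist must be list(dist = 'uniform', min, max) or ",
         "list(dist = 'normal', mean, sd)")
  }
  degenerate <- switch(gamma_dist$dist,
    uniform = gamma_dist$min == 0 && gamma_dist$max == 0,
    normal = gamma_dist$mean == 0 && gamma_dist$sd == 0)
  if (degenerate) {
    stop("degenerate config: all true exposure effects would be zero")
  }
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 gamma_dist = gamma_dist,
                 se_exposure_range = se_exposure_range,
                 se_outcome_range = se_outcome_range,
                 pleiotropy = pleiotropy,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_cor = pleiotropy_cor,
                 prop_invalid = prop_invalid,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws one harmonized-style instrument table under the generative model
#' of [simulation_config()]. The exposure-orientation convention is
#' applied (rows with a negative observed exposure effect are sign-flipped
#' in both betas, as [harmonize()] would do), and the truth columns are
#' flipped with them. Output is byte-identical across calls with the same
#' config; the caller's RNG state is untouched.
#'
#' @param config A [simulation_config()].
#' @return Data frame with the harmonized columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `proxy_of`, plus the simulation truth
#'   `gamma_true`, `alpha_true` and logical `invalid`.
#' @export
simulate_summary_stats <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must be created by simulation_config()")
  }
  with_seed(config$seed, {
    L <- config$n_snps
    g <- config$gamma_dist
    gamma <- switch(g$dist,
      uniform = stats::runif(L, g$min, g$max),
      normal = stats::rnorm(L, g$mean, g$sd))
    if (all(gamma == 0)) {
      stop("degenerate draw: all true exposure effects are zero")
    }
    sx <- stats::runif(L, config$se_exposure_range[1],
                       config$se_exposure_range[2])
    sy <- stats::runif(L, config$se_outcome_range[1],
                       config$se_outcome_range[2])

    n_invalid <- round(config$prop_invalid * L)
    invalid <- seq_len(L) %in% sample.int(L, n_invalid)
    alpha <- numeric(L)
    if (n_invalid > 0 && config$pleiotropy != "none") {
      m <- config$pleiotropy_mean
      s <- config$pleiotropy_sd
      alpha[invalid] <- switch(config$pleiotropy,
        balanced = stats::rnorm(n_invalid, 0, s),
        directional = stats::rnorm(n_invalid, m, s),
        inside_violating = {
          gi <- gamma[invalid]
          gs <- if (stats::sd(gi) > 0) (gi - mean(gi)) / stats::sd(gi)
                else rep(0, n_invalid)
          rho <- config$pleiotropy_cor
          m + s * (rho * gs +
                     sqrt(1 - rho^2) * stats::rnorm(n_invalid))
        })
    }
    bx <- stats::rnorm(L, gamma, sx)
    by <- stats::rnorm(L, config$theta * gamma + alpha, sy)
    flip <- bx < 0
    bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
    gamma[flip] <- -gamma[flip]; alpha[flip] <- -alpha[flip]
    data.frame(rsid = sprintf("snp_%04d", seq_len(L)),
               effect_allele = "A", other_allele = "G",
               beta_exposure = bx, se_exposure = sx,
               beta_outcome = by, se_outcome = sy,
               proxy_of = "", gamma_true = gamma, alpha_true = alpha,
               invalid = invalid, stringsAsFactors = FALSE)
  })
}

calibration_estimators <- function(names, wme_n_boot) {
  all <- list(
    ivw = function(dat, seed) mr_ivw(dat, effects_model = "random"),
    ml = function(dat, seed) mr_max_likelihood(dat),
    egger = function(dat, seed) mr_egger(dat)$slope,
    wme = function(dat, seed) {
      mr_weighted_median(dat, n_boot = wme_n_boot, seed = seed)
    })
  unknown <- setdiff(names, names(all))
  if (length(unknown)) {
    stop("unknown estimator(s): ", paste(unknown, collapse = ", "))
  }
  all[names]
}

#' Monte-Carlo calibration of the MR estimators
#'
#' Repeatedly simulates summary statistics under `config` and applies the
#' chosen estimators, aggregating mean bias, empirical SE, RMSE,
#' confidence-interval coverage of the true `theta`, and the rejection
#' rate of the two-sided t test at `alpha`, each with its Monte-Carlo
#' standard error. Replicate seeds are split from the master seed (a
#' seeded `sample.int` draw of one sub-seed per replicate for the
#' generator and one for each bootstrap), so any single replicate can be
#' reproduced independently. Estimator failures are counted and reported,
#' never silently dropped.
#'
#' The IVW estimator runs with multiplicative random-effects
#' studentization, the form whose t test is exactly calibrated under the
#' null; the weighted median uses a reduced bootstrap (`wme_n_boot`) for
#' speed.
#'
#' @param config A [simulation_config()] (its `seed` is the default
#'   master seed).
#' @param estimators Subset of `c("ivw", "ml", "egger", "wme")`.
#' @param n_reps Number of replicates (>= 100).
#' @param alpha Test level for the rejection rate (default 0.05).
#' @param seed Master seed; defaults to `config$seed`.
#' @param wme_n_boot Bootstrap size for the weighted median (default 200).
#' @return Object of class `calibration_report`: list with `summary`
#'   (one row per estimator: `estimator`, `n_ok`, `n_fail`, `mean_bias`,
#'   `bias_mc_se`, `empirical_se`, `rmse`, `coverage`, `coverage_mc_se`,
#'   `rejection`, `rejection_mc_se`), `estimates` (per-replicate betas),
#'   `n_reps`, `alpha`, and the echoed `config`.
#' @export
run_calibration <- function(config,
                            estimators = c("ivw", "ml", "egger", "wme"),
                            n_reps = 1000, alpha = 0.05, seed = NULL,
                            wme_n_boot = 200) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must be created by simulation_config()")
  }
  if (n_reps < 100) stop("n_reps must be at least 100")
  if (is.null(seed)) seed <- config$seed
  fns <- calibration_estimators(estimators, wme_n_boot)
  seeds <- with_seed(seed, matrix(sample.int(2^31 - 2, 2L * n_reps),
                                  ncol = 2L))
  theta <- config$theta

  beta <- matrix(NA_real_, n_reps, length(fns),
                 dimnames = list(NULL, names(fns)))
  cover <- reject <- matrix(NA, n_reps, length(fns),
                            dimnames = list(NULL, names(fns)))
  fails <- stats::setNames(integer(length(fns)), names(fns))
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seeds[i, 1L]
    dat <- simulate_summary_stats(cfg)
    for (nm in names(fns)) {
      res <- tryCatch(fns[[nm]](dat, seeds[i, 2L]), error = function(e) NULL)
      if (is.null(res)) {
        fails[nm] <- fails[nm] + 1L
        next
      }
      beta[i, nm] <- res$beta
      cover[i, nm] <- !is.na(res$ci_low) &&
        res$ci_low <= exp(theta) && exp(theta) <= res$ci_high
      reject[i, nm] <- !is.na(res$pvalue) && res$pvalue < alpha
    }
  }

  summarise_one <- function(nm) {
    b <- beta[, nm]
    ok <- !is.na(b)
    b <- b[ok]
    n <- length(b)
    cv <- mean(cover[ok, nm])
    rj <- mean(reject[ok, nm])
    data.frame(estimator = nm, n_ok = n, n_fail = fails[[nm]],
               mean_bias = mean(b) - theta,
               bias_mc_se = stats::sd(b) / sqrt(n),
               empirical_se = stats::sd(b),
               rmse = sqrt(mean((b - theta)^2)),
               coverage = cv, coverage_mc_se = sqrt(cv * (1 - cv) / n),
               rejection = rj, rejection_mc_se = sqrt(rj * (1 - rj) / n),
               stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, lapply(names(fns), summarise_one))
  rownames(summary) <- NULL
  structure(list(summary = summary, estimates = beta, n_reps = n_reps,
                 alpha = alpha, config = config),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, digits = 4, ...) {
  cat(sprintf("Calibration report: %d replicates, theta = %g, alpha = %g\n",
              x$n_reps, x$config$theta, x$alpha))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
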