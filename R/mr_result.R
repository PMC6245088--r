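#' Combined Mendelian randomization estimate
#'
#' Container for a combined causal estimate on the log-odds scale, with
#' Student-t inference. Constructed internally by the estimators
#' ([mr_ivw()], [mr_max_likelihood()], [mr_egger()],
#' [mr_weighted_median()]); users normally only read its fields.
#'
#' Inference convention: p-values and confidence limits use a t
#' distribution with `df` degrees of freedom (`L - 1` for combined
#' estimates over `L` SNPs, `L - 2` for the MR-Egger slope/intercept).
#' With `df = 0` (a single SNP) the p-value and CI are reported as `NA`.
#'
#' @param method Estimator label (`"wald"`, `"ivw"`, `"max_likelihood"`,
#'   `"egger_slope"`, `"weighted_median"`).
#' @param effects_model `"fixed"` or `"random"`.
#' @param beta Causal estimate, log-odds per unit of exposure.
#' @param se Standard error of `beta` (>= 0).
#' @param df Degrees of freedom for t-based inference.
#' @param n_snps Number of SNPs contributing to the estimate.
#' @param level Two-sided confidence level (default 0.95).
#'
#' @return An object of class `mr_result`: a list with elements `method`,
#'   `effects_model`, `n_snps`, `beta`, `se`, `or`, `ci_low`, `ci_high`
#'   (the latter three on the odds-ratio scale), `pvalue`, `df`, `level`.
#' @keywords internal
new_mr_result <- function(method, effects_model, beta, se, df, n_snps,
                          level = 0.95) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(se), length(se) == 1L, se >= 0,
            level > 0, level < 1)
  if (df >= 1 && se > 0) {
    tq <- stats::qt(1 - (1 - level) / 2, df = df)
    pvalue <- 2 * stats::pt(-abs(beta / se), df = df)
    ci <- beta + c(-1, 1) * tq * se
  } else if (df >= 1 && se == 0) {
    # degenerate (noiseless) estimate: point-mass CI, p undefined
    pvalue <- NA_real_
    ci <- c(beta, beta)
  } else {
    pvalue <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(
    list(method = method, effects_model = effects_model,
         n_snps = as.integer(n_snps), beta = beta, se = se,
         or = exp(beta), ci_low = exp(ci[1]), ci_high = exp(ci[2]),
         pvalue = pvalue, df = df, level = level),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf("Mendelian randomization estimate (%s, %s effects; %d SNPs)\n",
              x$method, x$effects_model, x$n_snps))
  cat(sprintf("  OR per exposure unit: %.*f (%d%% CI %.*f-%.*f)\n",
              digits, x$or, round(100 * x$level), digits, x$ci_low,
              digits, x$ci_high))
  cat(sprintf("  beta = %.*f, SE = %.*f, t df = %g, p = %s\n",
              digits + 1, x$beta, digits + 1, x$se, x$df,
              format(x$pvalue, digits = digits)))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, effects_model = x$effects_model,
             n_snps = x$n_snps, beta = x$beta, se = x$se, or = x$or,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             df = x$df, stringsAsFactors = FALSE)
}

#' Rescale a causal estimate to a different exposure unit
#'
#' Multiplies the log-odds estimate and its standard error by `factor` and
#' recomputes the confidence interval and p-value on the same degrees of
#' freedom. The t statistic, and hence the p-value, is unchanged. Used to
#' express an estimate per k exposure SD (for the serum-calcium instrument
#' 1 SD is 0.5 mg/dL, so the published scaling is `factor = 1`).
#'
#' @param result An [`mr_result`][new_mr_result].
#' @param factor Positive multiplier for the exposure unit.
#' @return A rescaled `mr_result`.
#' @export
#' @examples
#' r <- mr_ivw(data.frame(rsid = c("a", "b"), beta = c(0.1, 0.2),
#'                        se = c(0.05, 0.05)))
#' scale_estimate(r, 2)
scale_estimate <- function(result, factor) {
  if (!inherits(result, "mr_result")) stop("`result` must be an mr_result")
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("`factor` must be a single positive number")
  }
  new_mr_result(result$method, result$effects_model,
                result$beta * factor, result$se * factor,
                result$df, result$n_snps, result$level)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb user simulations.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
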