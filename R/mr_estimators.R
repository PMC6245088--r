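#' Per-SNP Wald-ratio causal estimates
#'
#' For each harmonized SNP the causal estimate is the ratio of the
#' SNP-outcome to the SNP-exposure effect, `beta = beta_outcome /
#' beta_exposure`, with a delta-method standard error. The first-order SE
#' (`se_outcome / |beta_exposure|`) treats the exposure effect as known
#' and is the default; the second-order SE adds the exposure sampling
#' term, `sqrt(se_outcome^2 / beta_exposure^2 + beta_outcome^2 *
#' se_exposure^2 / beta_exposure^4)`.
#'
#' @param dat Harmonized data frame (see [harmonize()]): columns `rsid`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param order `"first"` (default) or `"second"` delta-method order.
#' @return Data frame of ratio estimates: `rsid`, `beta`, `se`,
#'   `weight` (`= 1/se^2`).
#' @export
wald_ratio <- function(dat, order = c("first", "second")) {
  order <- match.arg(order)
  need <- c("rsid", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome")
  if (!all(need %in% names(dat))) {
    stop("`dat` must have columns: ", paste(need, collapse = ", "))
  }
  if (any(dat$beta_exposure == 0)) {
    stop("Wald ratio undefined (beta_exposure = 0) for: ",
         paste(dat$rsid[dat$beta_exposure == 0], collapse = ", "))
  }
  if (any(dat$se_outcome <= 0)) stop("se_outcome must be positive")
  beta <- dat$beta_outcome / dat$beta_exposure
  se <- switch(order,
    first = dat$se_outcome / abs(dat$beta_exposure),
    second = sqrt(dat$se_outcome^2 / dat$beta_exposure^2 +
                  dat$beta_outcome^2 * dat$se_exposure^2 /
                    dat$beta_exposure^4))
  data.frame(rsid = dat$rsid, beta = beta, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

# Accept either a harmonized SNP table or a ready-made ratio table.
as_ratio_estimates <- function(x, order = "first") {
  if (!is.data.frame(x)) stop("expected a data frame of SNPs or ratios")
  if ("beta_exposure" %in% names(x)) return(wald_ratio(x, order))
  if (!all(c("rsid", "beta", "se") %in% names(x))) {
    stop("ratio table must have columns rsid, beta, se")
  }
  if (any(x$se <= 0)) stop("ratio standard errors must be positive")
  x$weight <- 1 / x$se^2
  x
}

#' Inverse-variance weighted causal estimate
#'
#' Combines per-SNP Wald ratios with inverse-variance weights:
#' `beta = sum(w_i b_i) / sum(w_i)` with `w_i = 1/se_i^2`. The
#' fixed-effects SE is `1/sqrt(sum(w_i))`; the random-effects SE applies a
#' multiplicative overdispersion factor `sqrt(Q / (L - 1))` estimated from
#' Cochran's Q, which studentizes the estimate so that the t test with
#' `L - 1` degrees of freedom is exactly calibrated under homogeneity.
#' `effects_model = "auto"` uses the random-effects scaling only when
#' `Q > L - 1` (excess heterogeneity), and fixed effects otherwise.
#'
#' Inference (p-value and CI) uses a t distribution with `L - 1` degrees
#' of freedom; a single-SNP input returns the Wald ratio itself with `df =
#' 0` and an `NA` p-value.
#'
#' @param x Harmonized SNP table or ratio table (see [wald_ratio()]).
#' @param effects_model `"auto"` (default), `"fixed"`, or `"random"`.
#' @param level Confidence level (default 0.95).
#' @param order Delta-method order passed to [wald_ratio()] when `x` is a
#'   harmonized table.
#' @return An [`mr_result`][new_mr_result] with `method = "ivw"`.
#' @export
#' @examples
#' ratios <- data.frame(rsid = c("a", "b", "c"),
#'                      beta = c(-0.1, 0.0, 0.1), se = c(0.1, 0.1, 0.1))
#' mr_ivw(ratios, effects_model = "fixed")
mr_ivw <- function(x, effects_model = c("auto", "fixed", "random"),
                   level = 0.95, order = "first") {
  effects_model <- match.arg(effects_model)
  ratios <- as_ratio_estimates(x, order)
  L <- nrow(ratios)
  if (L < 1L) stop("at least one ratio estimate is required")
  w <- ratios$weight
  b <- ratios$beta
  beta <- sum(w * b) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  df <- L - 1L
  Q <- sum(w * (b - beta)^2)
  if (L == 1L) effects_model <- "fixed"
  if (effects_model == "auto") {
    effects_model <- if (Q > df) "random" else "fixed"
  }
  se <- if (effects_model == "random") se_fixed * sqrt(Q / df) else se_fixed
  new_mr_result("ivw", effects_model, beta, se, df, L, level)
}

#' Maximum-likelihood causal estimate
#'
#' Jointly models the SNP-exposure and SNP-outcome summary estimates as
#' independent normals, `beta_exposure_j ~ N(gamma_j, se_exposure_j^2)`
#' and `beta_outcome_j ~ N(theta * gamma_j, se_outcome_j^2)`, and
#' maximizes the likelihood over the L true exposure effects `gamma` and
#' the causal effect `theta`. Maximization alternates closed-form updates
#' of `gamma` given `theta` and `theta` given `gamma` (initialized at the
#' observed exposure effects and the fixed-effects IVW estimate) until the
#' change in `theta` falls below `tol`. The SE comes from the observed
#' information matrix, profiled over `gamma` by block inversion. In the
#' vanishing exposure-noise limit the estimator coincides with the
#' fixed-effects IVW estimate; rows with `se_exposure = 0` are treated as
#' exactly known.
#'
#' Inference uses t with `L - 1` degrees of freedom; with `effects_model
#' = "random"` (or `"auto"` when Cochran's Q exceeds its df) the SE is
#' inflated by the multiplicative overdispersion factor `sqrt(Q/(L-1))`
#' computed from the first-order Wald ratios.
#'
#' @param dat Harmonized SNP table (columns as in [wald_ratio()]).
#' @param effects_model `"auto"` (default), `"fixed"`, or `"random"`.
#' @param level Confidence level.
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on successive `theta` values
#'   (default 1e-10).
#' @return An [`mr_result`][new_mr_result] with `method =
#'   "max_likelihood"` and an attribute `convergence` (list with
#'   `iterations` and `converged`). On failure to converge an error of
#'   class `mr_ml_nonconvergence` is signalled whose condition carries
#'   the IVW estimate in `$ivw_fallback`.
#' @export
mr_max_likelihood <- function(dat, effects_model = c("auto", "fixed", "random"),
                              level = 0.95, max_iter = 200, tol = 1e-10) {
  effects_model <- match.arg(effects_model)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(dat))) {
    stop("`dat` must have columns: ", paste(need, collapse = ", "))
  }
  L <- nrow(dat)
  if (L < 2L) stop("at least two SNPs are required")
  bx <- dat$beta_exposure; sx <- dat$se_exposure
  by <- dat$beta_outcome; sy <- dat$se_outcome
  if (any(sy <= 0) || any(sx < 0)) stop("invalid standard errors")

  wx <- ifelse(sx > 0, 1 / sx^2, Inf)
  wy <- 1 / sy^2
  ivw <- mr_ivw(data.frame(rsid = dat$rsid,
                           beta = by / bx, se = sy / abs(bx)),
                effects_model = "fixed", level = level)
  theta <- ivw$beta
  converged <- FALSE
  iter <- 0L
  gamma <- bx
  while (iter < max_iter) {
    iter <- iter + 1L
    gamma <- ifelse(is.finite(wx),
                    (bx * wx + theta * by * wy) / (wx + theta^2 * wy),
                    bx)
    theta_new <- sum(gamma * by * wy) / sum(gamma^2 * wy)
    delta <- abs(theta_new - theta)
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(errorCondition(
      sprintf("maximum-likelihood estimate did not converge in %d iterations",
              max_iter),
      class = c("mr_ml_nonconvergence", "error", "condition"),
      ivw_fallback = ivw))
  }
  # profile the observed information over gamma: block inversion
  i_tt <- sum(gamma^2 * wy)
  i_gg <- wx + theta^2 * wy
  i_tg <- (2 * theta * gamma - by) * wy
  se <- 1 / sqrt(i_tt - sum(i_tg^2 / i_gg))

  df <- L - 1L
  Q <- local({
    r <- by / bx; w <- bx^2 / sy^2
    m <- sum(w * r) / sum(w)
    sum(w * (r - m)^2)
  })
  if (effects_model == "auto") {
    effects_model <- if (Q > df) "random" else "fixed"
  }
  if (effects_model == "random") se <- se * sqrt(Q / df)
  res <- new_mr_result("max_likelihood", effects_model, theta, se, df, L,
                       level)
  attr(res, "convergence") <- list(iterations = iter, converged = TRUE)
  res
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome effects on the
#' SNP-exposure effects with an unconstrained intercept, using weights
#' `1/se_outcome^2`. Under the InSIDE assumption the slope estimates the
#' causal effect adjusted for directional pleiotropy and the intercept is
#' the average directional-pleiotropy effect (log-odds per allele), giving
#' a formal test for directional pleiotropy. Standard errors use
#' multiplicative overdispersion scaled by `max(1, residual standard
#' error)`, so they are never deflated below the homoscedastic value;
#' slope and intercept are tested on t with `L - 2` degrees of freedom.
#'
#' Exposure effects must already be oriented non-negative (the convention
#' enforced by [harmonize()] and [simulate_summary_stats()]): the Egger
#' slope is not invariant to per-SNP reorientation.
#'
#' @param dat Harmonized SNP table (columns as in [wald_ratio()]).
#' @param constrain_intercept If `TRUE`, forces the intercept to zero
#'   (regression through the origin), in which case the slope reproduces
#'   the fixed-effects IVW estimate exactly; intended for testing.
#' @param level Confidence level.
#' @return An object of class `mr_egger_result`: a list with `slope` (an
#'   [`mr_result`][new_mr_result], `method = "egger_slope"`), `intercept`
#'   (list `estimate`, `se`, `or`, `pvalue`), `rse` (residual standard
#'   error), `n_snps`, `df`.
#' @export
mr_egger <- function(dat, constrain_intercept = FALSE, level = 0.95) {
  need <- c("beta_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(dat))) {
    stop("`dat` must have columns: ", paste(need, collapse = ", "))
  }
  L <- nrow(dat)
  if (L < 3L) stop("MR-Egger requires at least three SNPs")
  bx <- dat$beta_exposure; by <- dat$beta_outcome; sy <- dat$se_outcome
  if (any(bx < 0)) {
    stop("beta_exposure must be oriented non-negative before MR-Egger; ",
         "see harmonize()")
  }
  if (any(sy <= 0)) stop("se_outcome must be positive")
  if (length(unique(bx)) == 1L && !constrain_intercept) {
    stop("rank-deficient design: all exposure effects are identical")
  }
  w <- 1 / sy^2
  fit <- if (constrain_intercept) {
    stats::lm(by ~ 0 + bx, weights = w)
  } else {
    stats::lm(by ~ bx, weights = w)
  }
  s <- summary(fit)
  sigma <- s$sigma
  co <- s$coefficients
  df <- L - if (constrain_intercept) 1L else 2L
  # lm SEs already include sigma; rescale to max(1, sigma) overdispersion
  se_unit <- if (sigma > 0) co[, "Std. Error"] / sigma else co[, "Std. Error"]
  se_adj <- unname(se_unit * max(1, sigma))

  slope_i <- if (constrain_intercept) 1L else 2L
  slope <- new_mr_result("egger_slope",
                         if (sigma > 1) "random" else "fixed",
                         co[slope_i, "Estimate"], se_adj[slope_i], df, L,
                         level)
  intercept <- if (constrain_intercept) {
    list(estimate = 0, se = 0, or = 1, pvalue = NA_real_)
  } else {
    est <- co[1L, "Estimate"]; ise <- se_adj[1L]
    list(estimate = est, se = ise, or = exp(est),
         pvalue = if (ise > 0) 2 * stats::pt(-abs(est / ise), df = df)
                  else NA_real_)
  }
  structure(list(slope = slope, intercept = intercept, rse = sigma,
                 n_snps = L, df = df),
            class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, digits = 3, ...) {
  cat(sprintf("MR-Egger regression (%d SNPs, t df = %d, RSE = %.3f)\n",
              x$n_snps, x$df, x$rse))
  cat(sprintf("  Slope:     OR %.*f (%.*f-%.*f), p = %s\n",
              digits, x$slope$or, digits, x$slope$ci_low, digits,
              x$slope$ci_high, format(x$slope$pvalue, digits = digits)))
  cat(sprintf("  Intercept: %.*g (SE %.*g), OR %.*f, p = %s\n",
              digits, x$intercept$estimate, digits, x$intercept$se,
              digits, x$intercept$or,
              format(x$intercept$pvalue, digits = digits)))
  invisible(x)
}

weighted_median_point <- function(beta, weight, id = NULL) {
  ord <- if (is.null(id)) order(beta) else order(beta, id)
  b <- beta[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(b[1L])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Orders the per-SNP Wald-ratio estimates and takes the weighted median
#' under normalized inverse-variance weights: with cumulative percentile
#' positions `s_j = (cumulative weight) - w_j/2`, the estimate is linearly
#' interpolated at percentile 0.5. The weighted median is a consistent
#' estimate of the causal effect as long as SNPs carrying more than half
#' of the total weight are valid instruments. The standard error comes
#' from a seeded parametric bootstrap (each ratio resampled from
#' `N(beta_i, se_i^2)` with weights held fixed); inference uses t with
#' `L - 1` degrees of freedom. Ties in the sort are broken by rsid for
#' determinism.
#'
#' @param x Harmonized SNP table or ratio table.
#' @param n_boot Number of bootstrap replicates (default 10000; fewer
#'   than 100 is refused).
#' @param seed RNG seed for the bootstrap (default 1); the caller's RNG
#'   state is restored afterwards.
#' @param level Confidence level.
#' @param order Delta-method order for ratios from a harmonized table.
#' @return An [`mr_result`][new_mr_result] with `method =
#'   "weighted_median"`.
#' @export
mr_weighted_median <- function(x, n_boot = 10000, seed = 1, level = 0.95,
                               order = "first") {
  ratios <- as_ratio_estimates(x, order)
  L <- nrow(ratios)
  if (L < 3L) stop("weighted median requires at least three SNPs")
  if (n_boot < 100) stop("n_boot must be at least 100")
  est <- weighted_median_point(ratios$beta, ratios$weight, ratios$rsid)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(L * n_boot, mean = ratios$beta,
                                 sd = ratios$se),
                    nrow = L, ncol = n_boot)
    apply(draws, 2L, weighted_median_point, weight = ratios$weight)
  })
  se <- stats::sd(boots)
  new_mr_result("weighted_median", "fixed", est, se, L - 1L, L, level)
}

#' Cochran's Q heterogeneity statistics
#'
#' Tests homogeneity of the per-SNP causal estimates around the
#' fixed-effects IVW estimate: `Q = sum(w_i (b_i - b_ivw)^2)`, referred to
#' an upper-tail chi-square with `L - 1` degrees of freedom, and the
#' derived `I^2 = max(0, (Q - df)/Q) * 100` percentage of between-SNP
#' variability beyond chance.
#'
#' @param x Harmonized SNP table or ratio table.
#' @param order Delta-method order for ratios from a harmonized table.
#' @return An object of class `mr_heterogeneity`: list with `q`, `df`,
#'   `pvalue`, `i2` (percentage in `[0, 100)`), `n_snps`.
#' @export
mr_heterogeneity <- function(x, order = "first") {
  ratios <- as_ratio_estimates(x, order)
  L <- nrow(ratios)
  if (L < 2L) stop("heterogeneity requires at least two ratio estimates")
  w <- ratios$weight
  b <- ratios$beta
  beta <- sum(w * b) / sum(w)
  q <- sum(w * (b - beta)^2)
  df <- L - 1L
  structure(list(q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
                 n_snps = L),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, digits = 3, ...) {
  cat(sprintf("Cochran's Q = %.*f on %d df, p = %s; I^2 = %.1f%%\n",
              digits, x$q, x$df, format(x$pvalue, digits = digits), x$i2))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-applies a combining estimator L times, each time excluding one SNP,
#' to show whether the combined estimate is driven by any single variant.
#'
#' @param x Harmonized SNP table or ratio table with at least two rows.
#' @param estimator A function mapping a table like `x` to an
#'   [`mr_result`][new_mr_result] (default [mr_ivw()]).
#' @param ... Further arguments passed to `estimator`.
#' @return A data frame with one row per excluded SNP: `excluded`,
#'   `n_snps`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `pvalue`, `df`.
#'   Estimator errors are re-signalled with the excluded rsid named.
#' @export
mr_leave_one_out <- function(x, estimator = mr_ivw, ...) {
  if (!is.data.frame(x) || !"rsid" %in% names(x)) {
    stop("`x` must be a data frame with an rsid column")
  }
  L <- nrow(x)
  if (L < 2L) stop("leave-one-out requires at least two SNPs")
  rows <- lapply(seq_len(L), function(i) {
    res <- tryCatch(estimator(x[-i, , drop = FALSE], ...),
                    error = function(e) {
                      stop("leave-one-out excluding ", x$rsid[i], ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    cbind(excluded = x$rsid[i], as.data.frame(res)[
      c("n_snps", "beta", "se", "or", "ci_low", "ci_high", "pvalue", "df")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
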