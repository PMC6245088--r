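#' Proportion of exposure variance explained by an instrument
#'
#' For independent SNPs with per-allele effects in exposure-SD units,
#' `R^2 = sum(2 p (1 - p) beta^2)` where `p` is the effect-allele
#' frequency. Requires a frequency for every SNP.
#'
#' @param snps Data frame with columns `rsid`, an effect column
#'   (`beta_exposure` if present, else `beta`), and a frequency column
#'   (`eaf_exposure` if present, else `eaf`).
#' @return The summed R-squared (scalar in `[0, 1)`).
#' @export
variance_explained <- function(snps) {
  stopifnot(is.data.frame(snps))
  beta <- if ("beta_exposure" %in% names(snps)) snps$beta_exposure
          else snps$beta
  eaf <- if ("eaf_exposure" %in% names(snps)) snps$eaf_exposure
         else snps$eaf
  if (is.null(beta) || is.null(eaf)) {
    stop("`snps` must have effect (beta/beta_exposure) and frequency ",
         "(eaf/eaf_exposure) columns")
  }
  if (anyNA(eaf)) {
    stop("effect-allele frequency missing for: ",
         paste(snps$rsid[is.na(eaf)], collapse = ", "))
  }
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie in (0, 1)")
  sum(2 * eaf * (1 - eaf) * beta^2)
}

#' Instrument F-statistic
#'
#' First-stage strength of a k-SNP instrument explaining a fraction `r2`
#' of exposure variance in a sample of size `n`:
#' `F = (r2 / (1 - r2)) * ((n - k - 1) / k)`. Values well above 10
#' indicate that weak-instrument bias is unlikely.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Exposure-GWAS sample size (`n > k + 1`).
#' @param k Number of SNPs in the instrument (`k >= 1`).
#' @return The F-statistic (scalar, `>= 0`).
#' @export
#' @examples
#' f_statistic(0.0071, 61079, 5)
f_statistic <- function(r2, n, k) {
  stopifnot(is.numeric(r2), is.numeric(n), is.numeric(k))
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (k < 1) stop("k must be at least 1")
  if (n <= k + 1) stop("n must exceed k + 1")
  (r2 / (1 - r2)) * ((n - k - 1) / k)
}

#' I-squared-GX: expected regression dilution of MR-Egger
#'
#' Quantifies violation of the no-measurement-error (NOME) assumption for
#' MR-Egger: the expected attenuation of the Egger slope caused by
#' sampling noise in the SNP-exposure effects. It is an I-squared
#' statistic for the exposure effects: `Q_GX = sum(v_j (x_j - x_bar)^2)`
#' with `i2_gx = max(0, (Q_GX - (L-1)) / Q_GX)`. With
#' `weighting = "exposure"` the statistic is computed on `beta_exposure`
#' with `v_j = 1/se_exposure^2`; with `weighting = "egger"` (default) the
#' exposure effects are first placed on the Egger regression scale,
#' `x_j = beta_exposure_j / se_outcome_j` with SEs
#' `se_exposure_j / se_outcome_j`, so the weights match those of the
#' weighted Egger fit. Values near 1 mean negligible dilution.
#'
#' @param dat Harmonized SNP table with `beta_exposure`, `se_exposure`
#'   and (for `"egger"`) `se_outcome`; at least two SNPs.
#' @param weighting `"egger"` (default) or `"exposure"`.
#' @return Scalar in `[0, 1)`.
#' @export
i2_gx <- function(dat, weighting = c("egger", "exposure")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(dat))
  if (nrow(dat) < 2L) stop("i2_gx requires at least two SNPs")
  if (any(dat$se_exposure <= 0)) stop("se_exposure must be positive")
  if (weighting == "egger") {
    if (any(dat$se_outcome <= 0)) stop("se_outcome must be positive")
    x <- dat$beta_exposure / dat$se_outcome
    s <- dat$se_exposure / dat$se_outcome
  } else {
    x <- dat$beta_exposure
    s <- dat$se_exposure
  }
  v <- 1 / s^2
  mu <- sum(v * x) / sum(v)
  q <- sum(v * (x - mu)^2)
  if (q <= 0) return(0)
  max(0, (q - (nrow(dat) - 1L)) / q)
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Closed-form normal approximation: with `K` the case fraction of the
#' outcome study, `n` its total size, and `r2` the exposure variance
#' explained by the instrument, the non-centrality of the causal test is
#' `sqrt(n * r2 * K * (1 - K)) * |log(OR)|` and the two-sided rejection
#' probability at level `alpha` is
#' `pnorm(ncp - z) + pnorm(-ncp - z)` with `z = qnorm(1 - alpha/2)`.
#' Under the null (`OR = 1`) this returns exactly `alpha`.
#'
#' @param n Total outcome sample size (cases + controls).
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2 Exposure variance explained by the instrument, in `[0, 1)`.
#' @param odds_ratio Causal odds ratio per exposure SD to detect.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Rejection probability in `[0, 1]`.
#' @export
power_binary_outcome <- function(n, case_fraction, r2, odds_ratio,
                                 alpha = 0.05) {
  stopifnot(n > 0, case_fraction > 0, case_fraction < 1,
            r2 >= 0, r2 < 1, odds_ratio > 0, alpha > 0, alpha < 1)
  ncp <- sqrt(n * r2 * case_fraction * (1 - case_fraction)) *
    abs(log(odds_ratio))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Smallest detectable odds ratio at a target power
#'
#' Numerically inverts [power_binary_outcome()] by bisection on the
#' risk-increasing side (`OR > 1`), to a tolerance of 1e-6 on the OR
#' scale. The reciprocal is returned as the corresponding protective
#' bound.
#'
#' @inheritParams power_binary_outcome
#' @param target_power Desired power, must exceed `alpha`.
#' @return List with `or` (the OR > 1 solution) and `or_protective`
#'   (`1/or`).
#' @export
detectable_or <- function(n, case_fraction, r2, target_power, alpha = 0.05) {
  stopifnot(target_power < 1)
  if (target_power <= alpha) {
    stop("no solution: target power must exceed alpha")
  }
  f <- function(or) {
    power_binary_outcome(n, case_fraction, r2, or, alpha) - target_power
  }
  lo <- 1
  hi <- 1.05
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("no detectable OR below 1e6; instrument too weak")
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  or <- (lo + hi) / 2
  list(or = or, or_protective = 1 / or)
}

#' Bonferroni phenome-screen for pleiotropic instruments
#'
#' Screens candidate instrument SNPs against a table of cross-trait
#' association look-ups: each SNP's significance threshold is
#' `alpha / (number of look-ups performed for that SNP)`, and a SNP is
#' flagged (candidate horizontal pleiotropy) when any non-exposure trait
#' association falls below its threshold.
#'
#' @param lookups Data frame of look-ups: `rsid`, `trait`, `pvalue`.
#' @param n_lookups Named numeric vector (rsid -> number of look-ups), or
#'   a data frame with columns `rsid` and `n_lookups`. A count must be
#'   present for every rsid appearing in `lookups`.
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @param exposure_trait Optional trait label to exclude from flagging
#'   (the exposure itself).
#' @return List with `thresholds` (data frame `rsid`, `n_lookups`,
#'   `threshold`), `flagged` (character vector of flagged rsids) and
#'   `flagged_associations` (the sub-threshold look-up rows with their
#'   thresholds).
#' @export
#' @examples
#' bonferroni_screen(
#'   data.frame(rsid = "rs1", trait = "ldl", pvalue = 1e-6),
#'   c(rs1 = 859))
bonferroni_screen <- function(lookups, n_lookups, alpha = 0.05,
                              exposure_trait = NULL) {
  stopifnot(is.data.frame(lookups),
            all(c("rsid", "trait", "pvalue") %in% names(lookups)),
            alpha > 0, alpha < 1)
  if (is.data.frame(n_lookups)) {
    n_lookups <- stats::setNames(n_lookups$n_lookups, n_lookups$rsid)
  }
  if (any(n_lookups < 1)) stop("look-up counts must be at least 1")
  rsids <- unique(lookups$rsid)
  missing_counts <- setdiff(rsids, names(n_lookups))
  if (length(missing_counts)) {
    stop("no look-up count for: ", paste(missing_counts, collapse = ", "))
  }
  thresholds <- data.frame(rsid = names(n_lookups),
                           n_lookups = as.numeric(n_lookups),
                           threshold = alpha / as.numeric(n_lookups),
                           stringsAsFactors = FALSE)
  hits <- lookups
  if (!is.null(exposure_trait)) {
    hits <- hits[!(hits$trait %in% exposure_trait), , drop = FALSE]
  }
  hits$threshold <- thresholds$threshold[match(hits$rsid, thresholds$rsid)]
  hits <- hits[hits$pvalue < hits$threshold, , drop = FALSE]
  rownames(hits) <- NULL
  list(thresholds = thresholds,
       flagged = unique(hits$rsid),
       flagged_associations = hits)
}
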