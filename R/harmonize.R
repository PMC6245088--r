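COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses the SNP-exposure and SNP-outcome effects of each instrument
#' SNP on a shared effect allele, oriented so that the exposure effect is
#' non-negative (the exposure-increasing allele).
#'
#' For each exposure SNP the outcome row with the same rsid is used; if
#' absent and `proxy_map` supplies a proxy, the proxy's outcome row is used
#' and the harmonized row carries the proxy rsid with `proxy_of` recording
#' the original. Allele alignment: a swapped effect/other pair flips the
#' outcome beta sign and complements its frequency; if neither orientation
#' matches, the outcome alleles are strand-complemented once and the two
#' matches retried, after which an irreconcilable pair is a hard error
#' naming the rsid. Palindromic SNPs (A/T or C/G) are strand-ambiguous:
#' they are dropped when the effect-allele frequency is missing or within
#' `palindromic_eaf_limit` of 0.5, and otherwise aligned by frequency
#' concordance.
#'
#' @param exposure,outcome Data frames in the layout of
#'   [read_summary_table()] (unique rsids within each).
#' @param proxy_map Optional named character vector (or two-column data
#'   frame `source_rsid`/`proxy_rsid`) mapping exposure rsids to outcome
#'   proxy rsids.
#' @param palindromic_eaf_limit Drop palindromic SNPs whose exposure
#'   effect-allele frequency is within this distance of 0.5 (default
#'   0.08), or missing.
#' @return A list with elements
#'   \describe{
#'     \item{harmonized}{data frame: `rsid`, `effect_allele`,
#'       `other_allele`, `eaf_exposure`, `beta_exposure`, `se_exposure`,
#'       `beta_outcome`, `se_outcome`, `proxy_of` (empty string when no
#'       proxy was used); `beta_exposure >= 0` on every row.}
#'     \item{dropped}{data frame `rsid`, `reason` for SNPs excluded
#'       (unmatched, or palindromic and frequency-ambiguous).}
#'   }
#'   `nrow(harmonized) + nrow(dropped) == nrow(exposure)` always holds.
#' @export
harmonize <- function(exposure, outcome, proxy_map = NULL,
                      palindromic_eaf_limit = 0.08) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (anyDuplicated(exposure$rsid)) stop("duplicated rsid in exposure table")
  if (anyDuplicated(outcome$rsid)) stop("duplicated rsid in outcome table")
  if (is.data.frame(proxy_map)) {
    proxy_map <- stats::setNames(proxy_map$proxy_rsid, proxy_map$source_rsid)
  }

  rows <- vector("list", nrow(exposure))
  dropped <- list()
  drop <- function(rsid, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(rsid = rsid,
                                                   reason = reason,
                                                   stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    proxy_of <- ""
    j <- match(ex$rsid, outcome$rsid)
    if (is.na(j) && !is.null(proxy_map) && ex$rsid %in% names(proxy_map)) {
      j <- match(proxy_map[[ex$rsid]], outcome$rsid)
      if (!is.na(j)) proxy_of <- ex$rsid
    }
    if (is.na(j)) {
      drop(ex$rsid, "not present in outcome study (no usable proxy)")
      next
    }
    out <- outcome[j, ]

    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    if (pal && (is.na(ex$eaf) || abs(ex$eaf - 0.5) < palindromic_eaf_limit)) {
      drop(ex$rsid, "palindromic, frequency-ambiguous")
      next
    }

    ea <- out$effect_allele
    oa <- out$other_allele
    flip <- NA  # does the outcome effect allele need swapping?
    if (ea == ex$effect_allele && oa == ex$other_allele) flip <- FALSE
    else if (ea == ex$other_allele && oa == ex$effect_allele) flip <- TRUE
    else {
      # one strand complement, then retry both orientations
      ea <- unname(COMPLEMENT[ea]); oa <- unname(COMPLEMENT[oa])
      if (ea == ex$effect_allele && oa == ex$other_allele) flip <- FALSE
      else if (ea == ex$other_allele && oa == ex$effect_allele) flip <- TRUE
      else stop("alleles for ", out$rsid, " (outcome ", out$effect_allele,
                "/", out$other_allele, ") cannot be reconciled with exposure ",
                ex$effect_allele, "/", ex$other_allele)
    }
    beta_out <- if (flip) -out$beta else out$beta
    eaf_out <- if (flip) 1 - out$eaf else out$eaf
    if (pal && !is.na(ex$eaf) && !is.na(eaf_out) &&
        (ex$eaf - 0.5) * (eaf_out - 0.5) < 0) {
      # palindromic pair reported on opposite strands: frequencies disagree
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
    }

    effect_allele <- ex$effect_allele
    other_allele <- ex$other_allele
    eaf <- ex$eaf
    beta_exp <- ex$beta
    if (beta_exp < 0) {  # orient to the exposure-increasing allele
      tmp <- effect_allele; effect_allele <- other_allele; other_allele <- tmp
      eaf <- if (is.na(eaf)) NA_real_ else 1 - eaf
      beta_exp <- -beta_exp
      beta_out <- -beta_out
    }
    rows[[i]] <- data.frame(
      rsid = out$rsid, effect_allele = effect_allele,
      other_allele = other_allele, eaf_exposure = eaf,
      beta_exposure = beta_exp, se_exposure = ex$se,
      beta_outcome = beta_out, se_outcome = out$se,
      proxy_of = proxy_of, stringsAsFactors = FALSE)
  }

  harmonized <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(harmonized)) {
    harmonized <- data.frame(rsid = character(), effect_allele = character(),
                             other_allele = character(),
                             eaf_exposure = numeric(),
                             beta_exposure = numeric(),
                             se_exposure = numeric(),
                             beta_outcome = numeric(), se_outcome = numeric(),
                             proxy_of = character(), stringsAsFactors = FALSE)
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(rsid = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(harmonized) <- NULL
  list(harmonized = harmonized, dropped = dropped)
}
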