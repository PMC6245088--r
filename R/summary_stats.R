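#' Convert an odds ratio and confidence interval to log-OR and SE
#'
#' Inverts a published `OR (CI low - CI high)` cell to the log-odds scale:
#' `beta = log(OR)` and `se = (log(hi) - log(lo)) / (2 q)`, where `q` is the
#' two-sided quantile for the stated coverage (`qnorm` by default, `qt(df)`
#' when `df` is given). A degenerate interval (`lo == hi`) yields `se = 0`.
#'
#' Vectorized over all four numeric arguments.
#'
#' @param odds_ratio,ci_low,ci_high Positive odds ratio and confidence
#'   limits, with `ci_low <= odds_ratio <= ci_high`.
#' @param level Coverage of the interval (default 0.95).
#' @param df Degrees of freedom if the interval was built with Student-t
#'   quantiles; `NULL` (default) for normal quantiles.
#' @return A data frame with columns `beta` and `se`.
#' @export
#' @examples
#' beta_se_from_or_ci(0.84, 0.65, 1.09)   # beta -0.174, se 0.132
beta_se_from_or_ci <- function(odds_ratio, ci_low, ci_high, level = 0.95,
                               df = NULL) {
  stopifnot(is.numeric(odds_ratio), is.numeric(ci_low), is.numeric(ci_high),
            length(level) == 1L, level > 0, level < 1)
  if (any(odds_ratio <= 0) || any(ci_low <= 0) || any(ci_high <= 0)) {
    stop("odds ratio and confidence limits must be positive")
  }
  if (any(ci_low > ci_high)) stop("ci_low must not exceed ci_high")
  if (any(odds_ratio < ci_low) || any(odds_ratio > ci_high)) {
    stop("odds ratio must lie inside its confidence interval")
  }
  q <- ci_quantile(level, df)
  data.frame(beta = log(odds_ratio),
             se = (log(ci_high) - log(ci_low)) / (2 * q))
}

#' Convert a log-OR and SE to an odds ratio with confidence interval
#'
#' The inverse of [beta_se_from_or_ci()]: exponentiates
#' `beta +/- q * se` with the matching quantile, so the two functions
#' round-trip to machine precision for `se > 0`.
#'
#' @param beta Log odds ratio (vectorized).
#' @param se Standard error, `>= 0`.
#' @param df Degrees of freedom for Student-t quantiles; `NULL` for normal.
#' @param level Coverage (default 0.95).
#' @return A data frame with columns `odds_ratio`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' or_ci_from_beta_se(-0.017, 0.1966, df = 4)   # OR 0.98 (0.57-1.70)
or_ci_from_beta_se <- function(beta, se, df = NULL, level = 0.95) {
  stopifnot(is.numeric(beta), is.numeric(se))
  if (length(level) != 1L || !is.numeric(level) || level <= 0 || level >= 1) {
    stop("`level` must be a single number in (0, 1)")
  }
  if (any(se < 0)) stop("`se` must be non-negative")
  q <- ci_quantile(level, df)
  data.frame(odds_ratio = exp(beta),
             ci_low = exp(beta - q * se),
             ci_high = exp(beta + q * se))
}

ci_quantile <- function(level, df = NULL) {
  p <- 1 - (1 - level) / 2
  if (is.null(df)) stats::qnorm(p) else {
    if (!is.numeric(df) || any(df < 1)) stop("`df` must be >= 1")
    stats::qt(p, df = df)
  }
}

canonical_columns <- c("rsid", "chr", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pval", "n")
required_columns <- c("rsid", "effect_allele", "other_allele", "beta", "se")

#' Read a GWAS summary-association table
#'
#' Reads a tab-separated table with one row per SNP. Canonical headers are
#' `rsid, chr, effect_allele, other_allele, eaf, beta, se, pval, n`;
#' non-canonical headers are mapped through `column_map`. Missing values
#' are written as `"."` or left empty. Every parse or validation failure is
#' reported with its line number (header = line 1), and duplicated rsids
#' are an error.
#'
#' Validation: `se > 0`, `eaf` missing or in (0, 1), `pval` missing or in
#' (0, 1], alleles single bases A/C/G/T with `effect_allele !=
#' other_allele`.
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Optional named character vector mapping file headers
#'   to canonical names, e.g. `c(EA = "effect_allele", NEA = "other_allele")`.
#' @return A data frame with the canonical columns (missing optional
#'   columns filled with `NA`), rows in file order.
#' @seealso [write_summary_table()], [harmonize()]
#' @export
read_summary_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c(".", ""),
                           check.names = FALSE, strip.white = TRUE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map))) {
      stop("`column_map` must be a named character vector (file name -> canonical name)")
    }
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  }
  missing_cols <- setdiff(required_columns, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(canonical_columns, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[canonical_columns]

  nrows <- nrow(raw)
  lines <- seq_len(nrows) + 1L  # header occupies line 1
  problems <- character(0)
  note <- function(i, msg) {
    problems <<- c(problems, sprintf("line %d: %s", lines[i], msg))
  }

  num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    for (i in bad) note(i, sprintf("unparseable numeric in '%s': '%s'", col, x[i]))
    out
  }
  out <- data.frame(rsid = raw$rsid, chr = raw$chr,
                    effect_allele = toupper(raw$effect_allele),
                    other_allele = toupper(raw$other_allele),
                    eaf = num("eaf"), beta = num("beta"), se = num("se"),
                    pval = num("pval"), n = num("n"),
                    stringsAsFactors = FALSE)

  for (i in seq_len(nrows)) {
    if (is.na(out$rsid[i]) || !nzchar(out$rsid[i])) note(i, "missing rsid")
    for (col in c("effect_allele", "other_allele")) {
      a <- out[[col]][i]
      if (is.na(a) || !a %in% c("A", "C", "G", "T")) {
        note(i, sprintf("invalid %s: '%s'", col, a))
      }
    }
    if (!is.na(out$effect_allele[i]) && !is.na(out$other_allele[i]) &&
        out$effect_allele[i] == out$other_allele[i]) {
      note(i, "effect_allele equals other_allele")
    }
    if (is.na(out$beta[i])) note(i, "missing beta")
    if (is.na(out$se[i]) || (!is.na(out$se[i]) && out$se[i] <= 0)) {
      note(i, "se missing or not positive")
    }
    if (!is.na(out$eaf[i]) && (out$eaf[i] <= 0 || out$eaf[i] >= 1)) {
      note(i, "eaf outside (0, 1)")
    }
    if (!is.na(out$pval[i]) && (out$pval[i] <= 0 || out$pval[i] > 1)) {
      note(i, "pval outside (0, 1]")
    }
  }
  dup <- unique(out$rsid[duplicated(out$rsid)])
  dup <- dup[!is.na(dup)]
  if (length(dup)) {
    problems <- c(problems,
                  paste0("duplicated rsid: ", paste(dup, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid summary table '", path, "':\n  ",
         paste(problems, collapse = "\n  "))
  }
  out
}

#' Write a GWAS summary-association table
#'
#' Writes the canonical tab-separated layout used by
#' [read_summary_table()]; `NA` values are written as `"."`.
#'
#' @param x Data frame of SNP associations (canonical columns, or the
#'   harmonized layout of [harmonize()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Read a proxy-SNP map
#'
#' Two-column TSV (`source_rsid`, `proxy_rsid`) mapping an instrument SNP
#' absent from the outcome study to a linkage-disequilibrium proxy that is
#' present (the LD itself is taken as established upstream).
#'
#' @param path Path to the TSV file.
#' @return A named character vector: `names` are source rsids, values the
#'   proxy rsids.
#' @export
read_proxy_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", strip.white = TRUE)
  need <- c("source_rsid", "proxy_rsid")
  if (!all(need %in% names(x))) {
    stop("proxy map must have columns: ", paste(need, collapse = ", "))
  }
  stats::setNames(x$proxy_rsid, x$source_rsid)
}
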