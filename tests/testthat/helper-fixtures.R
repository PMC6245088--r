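# Small in-code fixtures shared across test files.

# A random ratio-estimate table (rsid, beta, se, weight).
random_ratios <- function(L, seed = 1, beta_sd = 0.3, se_range = c(0.05, 0.3)) {
  set.seed(seed)
  se <- runif(L, se_range[1], se_range[2])
  data.frame(rsid = sprintf("rs%03d", seq_len(L)),
             beta = rnorm(L, 0, beta_sd), se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

# A random harmonized table with known causal effect theta.
random_harmonized <- function(L, theta = 0.3, seed = 1,
                              sx = 0.01, sy = 0.05, intercept = 0) {
  set.seed(seed)
  gamma <- runif(L, 0.05, 0.3)
  data.frame(rsid = sprintf("rs%03d", seq_len(L)),
             beta_exposure = rnorm(L, gamma, sx), se_exposure = sx,
             beta_outcome = rnorm(L, theta * gamma + intercept, sy),
             se_outcome = sy, stringsAsFactors = FALSE)
}

# Canonical exposure / outcome association tables for harmonization tests.
assoc_row <- function(rsid, ea, oa, eaf, beta, se = 0.01, chr = "1") {
  data.frame(rsid = rsid, chr = chr, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pval = NA_real_, n = NA_real_,
             stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
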