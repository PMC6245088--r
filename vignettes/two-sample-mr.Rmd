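---
title: "Methods: two-sample Mendelian randomization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtwosample)
```

## The statistical problem

Two-sample Mendelian randomization treats germline genetic variants as
instrumental variables for an exposure: because alleles are assigned at
conception, SNP-exposure associations are (at population level) free of
the lifestyle confounding that distorts observational epidemiology. With
summary statistics only — per-SNP effect estimates on the exposure from
one GWAS and on a binary outcome from an independent GWAS — the causal
log-odds ratio per exposure SD, $\theta$, is identified for each valid
instrument SNP $j$ by the Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$.

Validity requires (i) a robust SNP-exposure association, (ii) no
association with confounders, and (iii) no path to the outcome except
through the exposure (exclusion restriction). The estimators in this
package differ in how much of (iii) they are willing to give up.

## Harmonization

Before any estimation the two tables must refer to the same allele.
`harmonize()` matches rows by rsid (with optional proxy substitution
through a user-supplied map; the linkage disequilibrium supporting a
proxy is taken as established upstream and is out of scope here), flips
the outcome beta and complements its allele frequency when the
effect/other alleles are swapped, tries a single strand complement before
declaring an allele pair irreconcilable, and finally orients every row so
the exposure effect is non-negative — the "exposure-increasing allele"
convention that MR-Egger requires.

Palindromic SNPs (A/T, C/G) cannot be strand-resolved from alleles
alone. The default policy drops them when the exposure effect-allele
frequency is missing or within 0.08 of 0.5, and otherwise aligns by
frequency concordance. The 0.08 window is a deliberately conservative
default — ambiguity grows continuously as the frequency approaches 0.5,
and instruments are usually few enough that dropping a borderline SNP is
cheaper than a silent sign error. The calcium instrument contains no
palindromic SNP, so the case study never exercises this rule.

## Estimators and inference

All combined estimates use Student-t inference: p-values and CIs from a t
distribution with $L-1$ degrees of freedom for IVW, maximum likelihood
and the weighted median, and $L-2$ for the MR-Egger slope and intercept.
With five-SNP instruments this is materially wider than normal inference
($t_{0.975,4} \approx 2.776$ vs 1.96) and is what reproduces the
published interval of the case study. Per-SNP (single-ratio) inference,
by contrast, uses normal quantiles: the published per-SNP intervals are
consistent with z-tests, which is why `build_calcium_fixture()` inverts
the OR/CI cells with normal quantiles and the combined tables with t.

**Wald ratio.** The delta-method SE defaults to first order,
$\sigma_{Yj}/|\hat\beta_{Xj}|$; the second-order form adding the
exposure-noise term is available by flag. First order is the convention
in the summary-data MR literature and keeps the weights independent of
the outcome effects.

**IVW.** Closed-form inverse-variance weighting. Three effects models:

* `fixed`: SE $= (\sum w_j)^{-1/2}$;
* `random`: multiplicative overdispersion, SE scaled by
  $\sqrt{Q/(L-1)}$ with $Q$ Cochran's statistic. The scaling is applied
  *unclamped*: under homogeneity $\hat\theta/\mathrm{SE_{fixed}}$ is
  standard normal and independent of $Q \sim \chi^2_{L-1}$, so the
  studentized ratio is exactly $t_{L-1}$ — the random-effects t test is
  exactly calibrated, which the type-I-error calibration test verifies
  empirically at 5,000 replicates. Clamping the factor at 1 (or using
  fixed SEs with t critical values) would make the test conservative by
  an order of magnitude at $L = 5$.
* `auto` (default): random iff $Q > L-1$, i.e. overdispersion is only
  ever applied upward. This matches the fixed-effects choice made in the
  case study, where $I^2 = 0\%$ for both outcomes.

**Maximum likelihood.** The joint model
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j, \sigma_{Yj}^2)$ (independent
errors; any exposure-outcome estimate correlation is assumed zero, as the
samples do not overlap) is maximized by alternating the closed-form
updates of $\gamma$ given $\theta$ and $\theta$ given $\gamma$,
initialized at the observed exposure effects and the fixed-effects IVW
estimate. Convergence is declared when successive $\theta$ values change
by less than $10^{-10}$, with a 200-iteration cap; non-convergence is a
typed error carrying the IVW estimate as a fallback, never a silent
substitution. The SE comes from the observed information, profiled over
$\gamma$ by block inversion. Rows with $\sigma_{Xj} = 0$ are treated as
exactly known, in which limit the estimator reduces to fixed-effects IVW
in closed form — the property used both as a test oracle and to run the
estimator on ratio-level fixtures (below).

**MR-Egger.** Weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with weights $1/\sigma_{Yj}^2$ and a free intercept,
which estimates the average directional-pleiotropy effect and, under the
InSIDE assumption, leaves the slope as a pleiotropy-adjusted causal
estimate. SEs are scaled by $\max(1, \mathrm{RSE})$ — overdispersion is
never allowed to shrink an SE below its homoscedastic value. A design
with identical exposure effects is rank-deficient and refused. A test
hook constraining the intercept to zero reproduces fixed-effects IVW to
$10^{-10}$, the identity used in testing.

**Weighted median.** Ratios are sorted (ties broken by rsid, for
determinism), weights normalized, and the estimate interpolated at the
50th weighted percentile using positions $s_j = \sum_{i \le j} w_i -
w_j/2$. The SE is a parametric bootstrap — each ratio resampled from
$N(\hat\theta_j, \mathrm{SE}_j^2)$ with weights held fixed — with
default `n_boot = 10000` and `seed = 1` (any fewer than 100 draws is
refused as meaningless); the bootstrap is bit-reproducible under its
seed and restores the caller's RNG state.

**Heterogeneity and leave-one-out.** Cochran's $Q$ around the
fixed-effects estimate, upper-tail $\chi^2_{L-1}$ p-value, and
$I^2 = \max(0, (Q-\mathrm{df})/Q)$ (reported as a percentage, defined as
0 when $Q = 0$). Leave-one-out reapplies any combining estimator $L$
times, labelling failures with the excluded rsid.

## Instrument diagnostics

* `variance_explained()`: $R^2 = \sum 2p_j(1-p_j)\beta_j^2$ for
  independent SNPs with effects in exposure-SD units; a missing
  frequency is an explicit, named error.
* `f_statistic()`: $F = \frac{R^2}{1-R^2}\cdot\frac{n-k-1}{k}$. For the
  calcium instrument ($R^2 = 0.0071$, $k = 5$), the exposure-GWAS
  per-SNP effects behind the published instrument-strength constants are
  not available at summary level, so the case study carries $R^2$ as a
  given constant and reports $F$ at the stated maximum sample size
  (87.3 at $n = 61{,}079$; 56.3 at the discovery $n = 39{,}400$) rather
  than asserting any printed value.
* `i2_gx()`: the no-measurement-error (NOME) dilution statistic for
  MR-Egger, an $I^2$ across the exposure effects. `"exposure"` weighting
  computes it on $(\hat\beta_{Xj}, \sigma_{Xj})$; the default `"egger"`
  weighting first divides both by $\sigma_{Yj}$ so the weights match the
  weighted Egger fit. It is invariant to rescaling all exposure effects
  and SEs by a common constant.
* `power_binary_outcome()`: closed-form normal approximation with
  non-centrality $\sqrt{nR^2K(1-K)}\,|\log \mathrm{OR}|$ ($K$ the case
  fraction). Both rejection tails are kept, so the null returns exactly
  $\alpha$. `detectable_or()` inverts it by bisection to $10^{-6}$ on
  the OR scale and returns the reciprocal protective bound. At the
  case-study face-value inputs ($n = 72{,}729$, $K = 0.616$,
  $R^2 = 0.0071$, OR 1.25) this formula gives power 0.69, not the 80%
  the source analysis reported; the parameterization behind that figure
  is not reconstructible, so the discrepancy is documented here and the
  power claims are covered by round-trip and monotonicity properties
  instead of a value assertion.
* `bonferroni_screen()`: per-SNP threshold $\alpha/(\text{look-ups})$
  over a static phenome look-up table; flagged SNPs are candidates for
  exclusion on horizontal-pleiotropy grounds. No live database is
  queried.

## The synthetic-data generator

`simulate_summary_stats()` draws exactly the structure the estimators
assume: true exposure effects $\gamma_j$ (uniform or normal), SEs
uniform on stated ranges, a pleiotropy effect $\alpha_j$ on an invalid
fraction of SNPs, and observed summaries
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$, then
applies the exposure-orientation convention. Pleiotropy regimes: none,
balanced (mean zero), directional (nonzero mean; InSIDE holds),
and InSIDE-violating ($\alpha$ correlated with $\gamma$). Defaults give
per-SNP F-statistics between roughly 10 and 100, straddling the
weak-instrument boundary; a configuration in which every true exposure
effect would be zero is refused as degenerate.

What the generator deliberately does **not** emulate: linkage
disequilibrium between instrument SNPs (instruments are assumed
independent, as real instruments are pruned to low $r^2$), sample
overlap between the two studies, individual-level confounding (pleiotropy
enters the outcome equation directly, which is sufficient to exercise
every summary-level estimator contract), binary-trait likelihood
non-normality, and allele-frequency structure. Passing calibration tests
therefore demonstrates correctness of the estimators under their own
assumptions — not robustness to LD, overlap, or selection effects in
real data.

`run_calibration()` repeats simulate-estimate cycles and aggregates
bias, empirical SE, RMSE, coverage and rejection with Monte-Carlo SEs.
Seeding: one master seed generates a pair of sub-seeds per replicate
(one for the generator, one for the weighted-median bootstrap) via a
single `sample.int` draw, so every replicate is independently
reproducible and the whole report is deterministic. Estimator failures
are counted per estimator and reported, never dropped silently.

Problem sizes used by the shipped calibration tests (chosen as the
smallest sizes at which the Monte-Carlo bands are meaningful): 5,000
replicates of a 5-SNP null instrument for the IVW type-I error; 200
replicates per point of a 3-point $\theta$ grid at $L = 50$ with tight
SEs for parameter recovery of all four estimators; 1,000 replicates at
$L = 100$ for Egger-intercept recovery of directional pleiotropy; 300
replicates per point across invalid fractions 0.3/0.5/0.7 for the
weighted-median breakdown. On the breakdown property: the weighted
median's finite-sample bias under 30% directional pleiotropy is not zero
— with 70% of weight valid the estimate sits near the 0.71 quantile of
the valid cluster, a shift of order half a ratio-SE that no number of
replicates averages away — so the test asserts the defensible form of
the robustness claim: far smaller bias than IVW below the 50% breakdown
point, and monotone degradation beyond it.

## The case study

`build_calcium_fixture()` embeds the five-SNP serum-calcium instrument
(effect alleles oriented to the calcium-increasing allele; the CASR SNP
is an LD proxy for the originally selected variant, recorded as such)
with its published per-SNP OR (95% CI) cells for overall and advanced
prostate cancer, inverts them with normal quantiles, and recomputes each
per-SNP z-test p-value for comparison with the printed column.

Two consequences of working from printed, 2-decimal-rounded cells are
handled explicitly rather than hidden:

* rounding propagates roughly 1-2% uncertainty into combined estimates;
  the tests therefore assert the overall combined OR within ±0.02 on the
  OR scale, and one per-SNP recomputed p-value differs from its printed
  value by 0.012 (asserted at ±0.015);
* MR-Egger genuinely cannot be run: it needs the separate SNP-exposure
  effect sizes, which are unpublished, and a ratio-level fixture has
  degenerate (identical) exposure effects. `run_calcium_case_study()`
  reports this as an explicit "not computable" field, and Egger is
  exercised on synthetic data instead. The maximum-likelihood estimator
  *is* run, in the exact-exposure limit (`beta_exposure = 1`,
  `se_exposure = 0`) where it coincides with IVW in closed form — so its
  case-study value is a genuine computation, though it can differ in the
  second decimal from a fit using the unpublished exposure effects.

The pipeline (IVW, ML, weighted median, heterogeneity, leave-one-out,
diagnostics, phenome screen) is deterministic given the embedded fixture
and the bootstrap seed, and writes TSV/JSON/plain-text reports when
given an output directory. The phenome-screen fixture lists the two SNPs
excluded from the instrument and their flagged trait classes; the
per-association p-values and per-SNP look-up counts in that fixture are
representative placeholders (the true values are not printed), which is
documented in its help page.

## Known limitations

Non-linear exposure effects are out of reach of summary-level MR;
penalized, mode-based and multivariable estimators, sample-overlap
corrections, Steiger directionality filtering and conditional
F-statistics are out of scope; proxy substitution aligns alleles between
the proxy and the outcome row but cannot check the sign of the LD phase
— users supplying proxies must supply them phase-consistent, as the
allele-matching error will otherwise be the only guard. The weighted
median's bootstrap SE assumes approximate normality of the per-SNP
ratios, which degrades for very weak instruments.
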