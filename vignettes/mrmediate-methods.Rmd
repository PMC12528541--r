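---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
library(dplyr)
```

## The model

mrmediate implements two-sample Mendelian randomization (MR) with a
two-step mediation extension, designed for questions of the form "does an
exposure (for example the abundance of a gut microbial taxon) causally
affect a disease, and how much of that effect flows through a circulating
mediator (for example a plasma metabolite)?" All inputs are GWAS summary
statistics: per-variant effect estimates, standard errors, alleles and
p-values, never individual-level data.

A genetic variant $j$ with effect $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) on
the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) on the outcome gives
the Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$. Under the
instrumental-variable assumptions (relevance, no confounding of the
variant-outcome relation, no effect on the outcome except through the
exposure), every valid variant estimates the same causal effect $\theta$,
and the estimators differ in how they pool and how they fail when the
third assumption (no horizontal pleiotropy) is violated:

* **IVW** — weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $1/\sigma_{Yj}^2$. We report the
  multiplicative random-effects standard error: the fixed-effect SE
  inflated by $\max\{1, \sqrt{Q/(J-1)}\}$, where $Q$ is Cochran's
  heterogeneity statistic. Under homogeneity this reduces exactly to the
  fixed-effect analysis, under heterogeneity it widens the interval
  without changing the point estimate; both SEs are retained in the
  result. Whether a fixed- or random-effects IVW is "the" primary
  analysis is a genuine choice; we default to the random-effects form
  because it is never anti-conservative relative to fixed effects, and
  measured its null behaviour (see below).
* **MR-Egger** — the same regression with a free intercept, after
  orienting all variants so $\hat\beta_{Xj} \ge 0$. The slope is a causal
  estimate robust to directional pleiotropy (under the InSIDE
  assumption); the intercept estimates the average directional
  pleiotropic effect and its test is reported as the pleiotropy
  diagnostic. Inference uses $t_{J-2}$ quantiles together with the
  $\max\{1, \sqrt{Q_{\mathrm{Egger}}/(J-2)}\}$ inflation, which is why
  Egger confidence intervals use $t$ critical values while all other
  methods use 1.96.
* **Weighted median** — the ratio at the point where standardized
  cumulative weights $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$
  (ratios sorted, weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$) cross
  0.5, by linear interpolation; consistent when at least half the weight
  comes from valid instruments. The interpolating formula is the
  definition; when one variant carries most of the weight the estimate
  equals (up to the interpolation) that variant's ratio. Its SE is a
  parametric bootstrap (default 1000 draws, seed-controlled) resampling
  both effect columns from their sampling distributions.

### Instrument selection

Candidates are variants below a p-value threshold — genome-wide
$5\times10^{-8}$ where instruments are plentiful, relaxed to
$1\times10^{-5}$ for microbiome-scale exposures and metabolites, and
$5\times10^{-5}$ for reverse analyses of a rare outcome, where the scan
warns (but never auto-relaxes) if fewer than 20 instruments emerge.
Greedy clumping then keeps, in p-value order, only variants with pairwise
$r^2 < 0.001$ within a 10 Mb window; linkage disequilibrium comes from a
user-supplied pairwise table (absent pairs mean $r^2 = 0$) rather than a
genotype reference panel, which keeps the package free of external
downloads and makes clumping exactly reproducible. Tie-breaking is
everywhere (p-value, variant id), for determinism.

Instrument strength is gated by
$F = \frac{R^2 (n - k - 1)}{k (1 - R^2)}$ with $k$ the number of variants
and $R^2$ the summed per-variant variance explained; sets with $F < 10$
are flagged weak and skipped. Per-variant $R^2$ is
$2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$ (unit-variance trait) when the
allele frequency is present, else the $t$-statistic form
$t^2/(t^2 + n - 2)$; both are standard, the frequency form is primary and
the choice is visible in the code path taken per record.

### Harmonization

Exposure orientation is canonical. Outcome records matching the exposure
allele pair (directly or after complementing both alleles, i.e. an
opposite-strand report) are kept; swapped pairs are kept with the outcome
beta negated and frequency reflected; palindromic variants (A/T, C/G) are
dropped unconditionally — no frequency-based rescue, since strand cannot
be resolved from the alleles; anything else is incompatible. Every action
is tallied and the tally always sums to the union of variant ids.
Missing-in-outcome variants are dropped (no proxy lookup).

### Sensitivity diagnostics

Cochran's $Q$ (ratio scale, IVW weights), the Egger intercept test,
leave-one-out IVW, and MR-PRESSO. MR-PRESSO simulates the null
distribution of the leave-one-out residual sum of squares (1000
parametric replicates by default), with add-one empirical p-values so the
smallest attainable p is $1/(n_{\mathrm{sim}}+1)$; per-variant outlier
tests are Bonferroni-adjusted across instruments at 0.05, matching common
practice. The distortion test compares the outlier-removal estimate shift
to removals of equally many variants, enumerated exhaustively when there
are at most 10,000 subsets and sampled otherwise — exactness when cheap,
bounded cost otherwise.

### Mediation

For an exposure with total effect $\beta$ (forward IVW), mediator
candidates are screened in two steps at $\alpha = 0.05$: exposure →
mediator ($\beta_1$, using the exposure's instruments) and mediator →
outcome ($\beta_2$, using the mediator's own instruments). Among passers,
mediators whose implied indirect effect $\beta_1\beta_2$ disagrees in
sign with $\beta$ are dropped as incongruent, and mediators whose step-2
odds-ratio confidence bound rounds onto 1.00 (within 0.005 after
two-decimal rounding) are dropped as unstable — a loggable proxy for
"broad interval, marginal significance". Exactly one mediator, the
congruent passer with the smallest step-2 p-value, is selected.

The decomposition is the product of coefficients: indirect
$= \beta_1\beta_2$, direct $= \beta - \beta_1\beta_2$, proportion
mediated $= \beta_1\beta_2/\beta$, reported as a percentage rounded to
two decimals. The identities hold to full precision, and pathological
proportions (incongruent signs, magnitude above 1) are reported with
`congruent = FALSE` rather than clamped — hiding them would mask exactly
the cases a user must see. No standard error is attached to the
proportion in the main table.

Multiple testing across an exposure family uses Benjamini–Hochberg
q-values computed over the family's IVW p-values (the most conservative
single-family reading). The forward scan reports both the suggestive tier
(uncorrected $p < 0.05$) and the corrected tier ($q < 0.05$); mediation
proceeds on suggestive hits and is therefore flagged exploratory in the
result object.

## The synthetic-data generator

`simulate_triple()` emulates the statistical structure of the three
summary-statistics sources the design needs, at their real scales by
default: a continuous exposure GWAS of 18,340 samples, a metabolite GWAS
of 8,299, and a binary outcome of 1,316 cases / 313,392 controls
(standard errors use the effective size
$4/(1/n_\mathrm{cases}+1/n_\mathrm{controls})$), with non-overlapping
samples by construction. Variants are in linkage equilibrium — clumped
independence is the state estimators actually receive, and LD handling is
exercised separately through explicit pairwise-$r^2$ fixtures. Minor
allele frequencies are uniform on (0.1, 0.5); standard errors are the
exact closed forms $1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,n}$ with no
extra noise, so tests can assert them exactly.

The planted causal diagram has two variant blocks. Exposure-block
variants carry effects $\gamma_j \sim N(0, 0.1^2)$ and reach the mediator
only as $\theta_1\gamma_j$ and the outcome as
$\theta_{\mathrm{total}}\gamma_j$ plus an optional pleiotropy offset.
Mediator-block variants instrument the mediator directly
($\delta_j \sim N(0, 0.12^2)$) and reach the outcome only as
$\theta_2\delta_j$. The second block is essential: if every variant acted
through the exposure, a mediator-instrumented MR would recover
$\theta_{\mathrm{total}}/\theta_1$ rather than $\theta_2$, and no
two-step analysis could be validated. The effect spreads were chosen once
so that a 30-variant block passes the $1\times10^{-5}$ selection
threshold for most variants (keeping winner's-curse selection effects
small relative to the recovery tolerances) while total variance explained
stays well below 1 — e.g. exposure instruments explain roughly 8–12% of a
unit-variance trait. Pleiotropy offsets are expressed relative to the
exposure-increasing allele, so a nonzero offset mean produces directional
pleiotropy under the $\hat\beta_X \ge 0$ orientation instead of cancelling
across arbitrary allele codings. Default planted effects are the
package's worked example: $\theta_{\mathrm{total}} = -0.507$,
$\theta_1 = 0.199$, $\theta_2 = -0.274$ (log-odds), a proportion mediated
of about 10.7%.

A configurable share of variants is palindromic (default 15%, about the
fraction seen on common genotyping arrays) and a share of outcome records
is emitted strand-complemented with unchanged beta (default 2%), which
harmonization must recover.

What the generator does **not** emulate: realistic LD structure,
winner's curse in the source GWAS themselves, allele-frequency
differences between cohorts, uncertainty in the outcome's binary-trait
scale approximation, and any biology connecting taxa to metabolites.
Passing recovery tests on this generator therefore demonstrates that the
estimators and the pipeline plumbing are correct under the stated
statistical model — not that any particular real-data finding would
replicate.

## Numerical and design choices

* p-values that underflow to zero on ingest (e.g. `1e-400`) are clamped
  to the smallest positive normal double, with a warning.
* Odds-ratio-scale sources are log-transformed at ingest (`effect_is_or`
  in the column map); all internal math is additive/log-odds.
* Empirical p-values (PRESSO global, per-variant, distortion) use the
  add-one estimator and are never zero.
* All stochastic components (weighted-median bootstrap, PRESSO, the
  generator) are reproducible from explicit seeds; re-running a scan with
  the same configuration is byte-identical.
* Degenerate inputs error early: zero exposure effects in ratio
  estimators, fewer than 3 variants for Egger/weighted median, fewer
  than 4 for PRESSO, duplicate variant ids in harmonization.

## Verification scale

The test suite validates estimators against independent normal-equations
and root-finding oracles on 5–10-variant fixtures (agreement to 1e-10),
and the statistical properties by Monte Carlo at the sizes reported by
`scripts/acceptance.R`: 400 null replicates of 30-variant instruments for
test size and interval coverage (IVW and the PRESSO global test both
reject about 3–5% of the time at nominal 5%; the random-effects IVW is
mildly conservative by construction, as the inflation floor only ever
widens intervals), 200 replicates for recovery of a planted total effect
of −0.5 and proportion mediated of 11%, and 100 replicates for
planted-outlier power (a 10-SE offset is flagged essentially always, and
its removal decreases Cochran's Q in every replicate observed).

## Known limitations

* No proxy-variant lookup for missing outcome records, no Steiger
  directionality filtering, no multivariable MR, no mode-based or RAPS
  estimators.
* LD must be supplied as a pairwise table; there is no reference-panel
  computation, so clumping quality is only as good as the supplied table.
* The mediation stage selects a single mediator per exposure by design;
  joint or sequential multi-mediator decompositions are out of scope.
* The proportion mediated has no interval in the main output; a
  delta-method SE would understate uncertainty when the total effect is
  near zero, which is exactly where proportions explode.
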