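---
title: "Two-sample Mendelian randomisation with mrpipe: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomisation with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Mendelian randomisation (MR) estimates the causal effect $\beta$ of an
exposure $X$ on an outcome $Y$ using genetic variants $Z_j$ as instrumental
variables. A valid instrument (i) associates with the exposure, (ii) shares
no unmeasured confounder with the outcome, and (iii) affects the outcome
only through the exposure. In the two-sample summary-level setting, the
inputs are per-SNP marginal association estimates from two independent
GWAS: $\hat\gamma_{E,j}$ (SNP on exposure) and $\hat\gamma_{O,j}$ (SNP on
outcome), each with a standard error. The single-instrument estimate is the
Wald ratio $\hat\beta_j = \hat\gamma_{O,j} / \hat\gamma_{E,j}$; with many
approximately independent instruments the ratios are pooled
meta-analytically.

`mrpipe` implements the full workflow around that estimate: reading and
harmonising summary tables, instrument selection and strength metrics, an
estimator battery, outlier handling, the standard sensitivity toolkit, bulk
screening over many trait pairs, and — as a complementary individual-level
method — linear-Gaussian Bayesian-network structure learning with genetic
directional anchors.

## Data preparation

**Harmonisation.** `harmonise()` aligns the outcome file's effect alleles to
the exposure file's. Swapped labels negate the outcome beta and complement
its allele frequency; strand-complementary labels are complemented first.
Palindromic variants (A/T, C/G) cannot be aligned from labels alone, so they
are resolved by allele-frequency agreement and dropped whenever either
frequency is missing or within 0.08 of 0.5 (minor-allele frequency above
0.42). The window is configurable; 0.08 mirrors common two-sample practice
and errs toward dropping ambiguous variants. Dropped rows are retained in
the output with a flag but carry `NA` associations, so they can never reach
an estimator.

**Instrument selection and strength.** `select_instruments()` applies the
conventional genome-wide threshold $p < 5\times10^{-8}$ (strict inequality);
$10^{-6}$ and $10^{-12}$ are the usual liberal/conservative alternatives,
and `threshold_scan()` repeats the analysis across such a grid.
`instrument_strength()` reports per-SNP $R^2 = t^2/(t^2 + n - 2)$ and
$F = (n-2)R^2/(1-R^2)$, which reduces algebraically to $t^2$; the
test-statistic form is the default because it needs neither allele
frequencies nor unit conventions, while the frequency-based
$2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$ variant is available and flagged.
A mean $F > 10$ is the conventional guard against weak-instrument bias.

**LD pruning.** `ld_prune()` performs greedy selection in ascending p-value
order (ties broken by SNP id, so outputs are deterministic), keeping a SNP
only when its $r^2$ with every kept SNP is at most the threshold (default
0.001). Without an LD matrix the function is a logged no-op rather than an
error: most public summary sources are pre-clumped, and the synthetic
generator emits independent SNPs.

## Estimators

* `mr_ivw()` pools ratios with inverse-variance weights
  $w_j = 1/\mathrm{se}_j^2$ using first-order ratio SEs
  $\mathrm{se}_j = \mathrm{se}_{O,j}/|\hat\gamma_{E,j}|$ by default (the
  no-measurement-error approximation; second-order SEs adding the
  exposure-uncertainty term are available). Three meta-analytic variants:
  fixed effects; multiplicative random effects (the default), which keeps
  the fixed-effects point estimate and inflates the SE by
  $\sqrt{\max(1, Q/(J-1))}$; and additive random effects with the
  DerSimonian–Laird $\tau^2$. The multiplicative default reflects the usual
  recommendation under heterogeneity: it never moves the point estimate and
  the over-dispersion factor is floored at 1 so heterogeneity can only widen
  intervals, never tighten them.
* `mr_egger()` frees the intercept: weighted least squares of
  $\hat\gamma_O$ on $\hat\gamma_E$ after orienting all instruments to
  non-negative exposure associations. A non-zero intercept flags directional
  pleiotropy; the slope is consistent under the InSIDE assumption. Because
  the fit estimates two parameters from typically modest $J$, inference uses
  a $t$ distribution with $J-2$ degrees of freedom and the same
  multiplicative over-dispersion floor.
* `mr_weighted_median()` interpolates the ratio at standardised cumulative
  weight 0.5 and is consistent when valid instruments hold at least half
  the weight. `mr_weighted_mode()` maximises a weighted Gaussian kernel
  density over the ratios (bandwidth
  $\varphi \cdot 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)J^{-1/5}$, a
  modified Silverman rule with user factor $\varphi$, evaluated on a
  512-point grid spanning the ratio range plus three bandwidths) and is
  consistent when the largest like-valued group is valid. Both take their
  SEs from a parametric bootstrap that resamples the summary associations
  from normals with their reported SEs — consistent with the summary-data
  likelihood, unlike pair resampling — and both require an explicit seed.
* `mr_mvmr_ivw()` regresses the outcome associations on a $J \times K$
  matrix of exposure associations without intercept, estimating each
  exposure's direct effect controlling for the others.
* `mr_presso()` implements the three-part outlier analysis: a global
  heterogeneity test on the weighted residual sum of squares about
  leave-one-out IVW predictions, per-SNP outlier tests
  (Bonferroni-adjusted), and a distortion test comparing the
  outlier-removed estimate shift against random same-size removals. All
  null distributions are parametric simulations from the reported summary
  statistics; both association vectors are resampled by default (an
  outcome-only fast variant exists). Empirical p-values use the
  $(r+1)/(n_{\mathrm{sim}}+1)$ rule and can never be exactly zero.
* `mr_mediation()` provides the two classical indirect-effect estimates —
  difference $\hat\beta_{tot} - \hat c$ and product $\hat a \hat b$ — which
  correspond to the multivariable-MR and two-step-MR framings and agree
  asymptotically in linear-Gaussian systems.

## Sensitivity analysis

`sensitivity_report()` assembles the standard battery for one harmonised
pair: Cochran's $Q$ and Higgins' $I^2$ (against both the fixed-effects IVW
fit, $df$-adjusted by 1, and the Egger fit, adjusted by 2), the Egger
intercept triple, leave-one-out and single-SNP tables, funnel and scatter
plot data, and the Steiger directionality test. `mr_steiger()` compares
aggregate variance explained via Fisher's $z$ on the two aggregate
correlations; `steiger_filter()` applies the same comparison per SNP.
For binary outcomes the $t$-statistic correlations are used unchanged (an
observed-scale approximation, flagged here because no scale conversion is
attempted). `mr_bidirectional()` orchestrates both causal directions;
a direction without instruments is a first-class `"not_estimable"` result
rather than an error, because bulk screening must never abort on one pair.

## The synthetic-data generator

`simulate_two_sample()` realises the standard causal diagram: independent
biallelic genotypes $Z_j \sim \mathrm{Bin}(2, \mathrm{maf}_j)$, exposure
$X = \sum_j \gamma_j Z_j + \kappa_x U + \varepsilon_x$, outcome
$Y = \beta X + \sum_j \alpha_j Z_j + \kappa_y U + \varepsilon_y$ with a
latent confounder $U$. The pleiotropy regimes set $\alpha_j$: zero
(`none`), mean-zero (`balanced`), non-zero mean $\mu_\alpha$
(`directional`), or $\theta\gamma_j$ plus noise (`correlated`, violating
InSIDE); `pleio_prob` restricts the direct effects to a fraction of
instruments. Sample overlap shares leading individuals between cohorts, and
an optional logistic selection rule in $(X, Y, U)$ induces collider bias.
Individual-level generation followed by per-SNP marginal regression makes
those mechanisms arise exactly as in real data; a `direct` mode draws the
summary estimates straight from their asymptotic sampling distributions
(same first two moments) and is used for replicate-heavy calibration loops.

Defaults describe a well-powered study: $J = 100$ independent instruments,
$\gamma_j \sim N(0.05, 0.01^2)$ trait-SD per allele, minor-allele
frequencies uniform on $(0.05, 0.5)$, 50,000 individuals per cohort
(mean $F \approx 33$), causal effect $\beta = 0.1$, confounder loadings
0.3, unit residual noise. These were fixed once as a realistic
population-biobank regime. What the generator does **not** emulate: LD
between instruments (pruning is exercised through user-supplied matrices),
dynastic/assortative-mating structure, and time-varying exposures — so
passing tests say nothing about those features of real data.

## Validation choices and problem sizes

The packaged checks run the whole stack at these sizes, chosen to make
Monte-Carlo error small while keeping the default test run fast:
parameter recovery and coverage with 200 replicates of the default regime;
type-I error of multiplicative-RE IVW with 500 null replicates under
balanced pleiotropy; Egger intercept recovery with 200 replicates of
directional pleiotropy $\mu_\alpha = 0.02$ at an exposure GWAS of 500,000 —
the strong-instrument regime matters because with noisier exposure
associations the Egger intercept shows the well-known weak-instrument
dilation, and widening the spread of $\gamma$ instead produces occasional
sign flips whose re-orientation places high-leverage points near zero and
biases the intercept downward; median-vs-IVW robustness with 30% invalid
instruments carrying $\mu_\alpha = 0.05$, a contamination shift chosen to
be material relative to valid-instrument ratio noise; MR-PRESSO power on a
planted 10-outcome-SE outlier and null size at $n_{\mathrm{sim}} = 1000$
over 200 replicates each; $Q$ calibration against $\chi^2_{J-1}$ over 2000
replicates constructed with negligible exposure-side error, the regime in
which first-order weights make that reference exact; and bootstrap network
recovery at 200 resamples.

## Screening and Bayesian networks

The exploratory screen (`filter_heritable()`, `filter_correlated()`,
`screen_pairs()`) consumes heritability estimates (with an ordered
confidence label, supplied in the input because it is an annotation of the
source database) and phenotype correlations, applying the printed
thresholds as strict inequalities; a reported p-value of exactly zero is
treated as infinitely significant. Screening output is labelled
exploratory and is uncorrected by design — instruments selected and tested
on the same associations inflate hits — with a Bonferroni-adjusted column
emitted alongside.

`hill_climb()` learns a DAG by greedy single-edge moves (add, delete,
reverse) under a decomposable Gaussian BIC, starting from the
whitelist-only graph; whitelisted edges are never deleted or reversed and
blacklisted edges never added. SNP dosages are treated as numeric 0/1/2
regressors, which matches their role as directional anchors; multinomial
nodes are out of scope. `bootstrap_edges()` tallies adjacency presence and
orientation over nonparametric row resamples (resample size $n$, the
standard choice): the presence threshold (default 0.8) governs which
adjacencies enter the consensus graph, while orientation needs only a
majority given presence, because the two probabilities answer different
questions. Singular parent designs are scored by pseudo-inverse with a
degeneracy flag instead of failing; rare consensus cycles are broken by
dropping the lowest-presence edge; plain hill climbing is the default,
with optional seeded random restarts.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_snps = 100, beta = 0.1, seed = 42)
study <- simulate_two_sample(cfg)
h <- harmonise(study$exposure, study$outcome)
mr_battery(h, seed = 1)
sensitivity_report(h, seed = 1)
```

## Known limitations

First-order ratio SEs understate uncertainty for weak instruments
(second-order SEs are one call away). The Egger intercept inherits
weak-instrument dilation as described above. Steiger filtering is sensitive
to differential measurement error between the two GWAS. The direct
simulation mode approximates overlap-induced error correlation to first
order and cannot represent selection. The network learner is
continuous-only and returns a single DAG per run rather than an
equivalence class.
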