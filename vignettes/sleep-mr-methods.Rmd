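---
title: "Methods: one-sample and factorial MR for survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample and factorial MR for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmr)
library(dplyr)
```

## The problem

Observational associations between sleep traits and cardiovascular disease
are confounded (lifestyle, socioeconomic position, comorbidity), subject to
reverse causation (early disease disrupts sleep) and measured with error.
Mendelian randomization (MR) sidesteps these by using genetic variants —
fixed at conception and randomly allocated — as instruments for the
exposure. This package implements the one-sample MR design for a censored
time-to-event outcome (incident acute myocardial infarction in the
motivating application), plus a factorial extension that asks whether two
exposures *interact* on the additive scale rather than merely both mattering.

Because the individual-level cohorts such analyses run on (UK Biobank-scale
or regional health-survey-scale) are access-restricted, the package treats
the data-generating process itself as a first-class module: a synthetic
cohort generator reproduces the assumed causal structure so that every
estimator can be validated end to end, at known truth, on a laptop.

## The estimator: two-stage predictor substitution with a Cox second stage

Let $G$ be a genetic risk score, $X$ the exposure, $C$ covariates, and
$(T, \delta)$ the censored event time and indicator.

* **Stage 1.** Regress $X$ on $G$ and $C$ — ordinary least squares for a
  continuous exposure, logistic regression for a binary one. The fit is
  restricted to participants who did not experience the event during
  follow-up: with a binary/ survival outcome, including cases in the
  first stage lets the outcome leak into the fitted exposure. The fitted
  values $\hat X$ are then computed for *all* participants by applying the
  non-case coefficients to everyone's $(G, C)$ — the restriction concerns
  fitting, not prediction; this is the only reading under which cases have
  fitted values at all.
* **Stage 2.** Fit a Cox proportional-hazards model of $(T, \delta)$ on
  $\hat X$ and the same $C$ (Efron tie handling — the more accurate default,
  and tied times are common at yearly resolution). The coefficient
  $\hat\beta$ on $\hat X$ is the causal log hazard ratio.

For binary exposures the stage-1 fitted values enter stage 2 on the
**linear-predictor (log-odds) scale** by default. This makes the customary
"per doubling of odds" rescaling exact: multiplying $\hat\beta$ (per unit
log-odds) by $\ln 2 = 0.693$ gives the effect per doubling of the odds of
the exposure, since $\exp(0.693\,\beta) = 2^\beta$. A predicted-probability
scale is available (`stage1_scale = "probability"`) but breaks that exact
correspondence, which is why it is not the default.

**Uncertainty.** The two-stage point estimate treats $\hat X$ as known, so
model-based Cox standard errors are too small. `tsps_cox()` bootstraps
participants, rerunning the complete two-stage procedure on each resample;
the SE is the standard deviation of replicate estimates, and the canonical
CI is the normal approximation $\hat\beta \pm 1.96\,\widehat{se}$ (a
percentile interval is reported alongside). Replicate seeds derive from the
master seed through a counter, so changing the iteration count never
silently reorders streams, and fits that fail on degenerate resamples are
tallied — more than 5% failures aborts rather than returning a quietly
biased SE. Defaults of 2000 iterations suit cohorts of hundreds of
thousands; smaller or noisier cohorts warrant more (the motivating analyses
used 2000 and 5000 in their two cohorts).

**What the estimator does and does not promise.** The TSPS point estimate
inherits the usual one-sample MR caveats: with a finite-strength instrument
and confounding, estimates are pulled slightly toward the confounded
association, and the Cox hazard ratio is non-collapsible. In the package's
own 200-replicate calibration (true HR 1.25 per unit, F ≈ 120) the mean
recovered HR sits a few percent above the truth while bootstrap-CI coverage
is at its nominal 95% — the interval, not the point, is the reliable
summary at moderate instrument strength.

## Factorial MR and RERI

`assign_2x2_groups()` splits each of two scores at its sample median, ties
going low — the published convention "values equal to or below the median
represent low genetic risk" is followed exactly. The cross defines four
groups; a Cox model on the three non-reference indicators (plus covariates)
gives $HR_{10}, HR_{01}, HR_{11}$ and their log-scale covariance (robust by
default). Additive interaction is

$$\mathrm{RERI} = HR_{11} - HR_{10} - HR_{01} + 1,$$

zero under exact additivity of excess risks. Its CI uses the delta method on
the jointly normal log HRs, with gradient $(-HR_{10}, -HR_{01}, HR_{11})$;
`reri_from_hrs(n_boot = )` adds a parametric-bootstrap interval from
multivariate-normal draws as a cross-check (the two agree closely in tests).
Following the convention in the interaction literature, RERI is only
reported when none of the three HRs is preventive (< 1); an `force = TRUE`
override exists for methodological work, and the package warns rather than
silently emitting a number. Note the algebraic consequence tested in the
suite: exactly multiplicative joint effects give
$\mathrm{RERI} = (HR_{10}-1)(HR_{01}-1) \ge 0$, so a null RERI is evidence
of additivity, not of "no joint effect".

The continuous variant (`continuous_factorial_cox()`) standardizes both
scores to unit SD, fits $z_A + z_B + z_A z_B$, and evaluates RERI at +1 SD
in both scores, $e^{b_1+b_2+b_3} - e^{b_1} - e^{b_2} + 1$ — the natural
contrast once effects are reported per SD, avoiding the information loss of
dichotomization.

## Genetic risk scores

`harmonize_weights()` aligns external GWAS weights to the counted allele.
When the weight's effect allele is the non-counted allele, the package
negates the beta and reflects the frequency rather than rewriting dosages
(one convention, applied everywhere and stated in the documentation; the
two are equivalent up to an intercept absorbed by the regressions).
Unmatched variants and irreconcilable allele pairs are dropped with an
explicit report, never silently. Palindromic (A/T, C/G) variants are flagged
and kept by default; `strict = TRUE` drops those with effect-allele
frequency in [0.42, 0.58], where strand cannot be resolved from frequency.

Weighted scores are $\sum_j \beta_j d_j$; unweighted scores count
trait-increasing alleles, reflecting the dosage of negative-beta variants so
both flavours point the same direction (unweighted scores are the right
choice when the discovery GWAS overlaps the analysis cohort, where internal
weights would import winner's-curse bias). Instrument strength is reported
as the $R^2$ and F from regressing the exposure on the score; for binary
exposures the default is the observed-scale linear-probability $R^2$ (a
single reproducible number; McFadden's pseudo-$R^2$ is available as an
option). For one regressor $F = R^2 (n-2) / (1 - R^2)$, an identity the
tests assert.

## Summary-statistic sensitivity estimators

From the same cohort, `per_snp_associations()` estimates each variant's
exposure effect $\gamma_j$ (non-cases only, mirroring the TSPS stage-1
restriction — the convention is recorded here because the source analyses
are silent at the per-variant level) and outcome log hazard ratio
$\Gamma_j$. On these, the package implements the standard estimator panel:

* **IVW** — weighted regression of $\Gamma$ on $\gamma$ through the origin,
  weights $1/se_\Gamma^2$;
* **MR-Egger** — the same with an intercept, after orienting all $\gamma_j
  \ge 0$; the intercept estimates average directional pleiotropy, and the
  slope is valid under the InSIDE assumption. With the intercept constrained
  to zero, it reduces exactly to IVW (a tested identity). Applied within a
  single sample, MR-Egger can be unreliable; it is here as a consistency
  probe, matching its role in the motivating study;
* **simple/weighted median** — the ratio estimates $\Gamma_j/\gamma_j$
  combined by inverting the midpoint cumulative weight function at 0.5
  (weights equal, or $\gamma_j^2/se_{\Gamma_j}^2$); valid if at least half
  the weight is on valid instruments;
* **weighted mode** — the argmax of an inverse-variance-weighted Gaussian
  kernel density over the ratio estimates; valid under a plurality of valid
  instruments. The bandwidth is $\phi \cdot 0.9 \min(sd, mad) \cdot
  m^{-1/5}$ with $\phi = 1$ by default — the normal-reference rule on the
  ratio spread; $\phi$ is exposed because no published value exists for this
  estimator's bandwidth in the source analyses.

Median and mode SEs use a parametric bootstrap (redrawing each
$\gamma_j, \Gamma_j$ from normals with their estimated SEs) — the standard
and much cheaper choice for summary-level estimators, rather than
re-resampling participants. IVW/Egger standard errors use the multiplicative
random-effects convention with dispersion floored at 1, so heterogeneity
widens but never narrows intervals.

## Diagnostics

`ph_schoenfeld_test()` correlates each term's Schoenfeld residuals with
event time (Pearson, two-sided) — the proportional-hazards check used in
the motivating study, equivalent to `cox.zph` on identity-transformed time.
`confounder_scan()` regresses each candidate confounder on each
standardized score and flags associations beyond the Bonferroni threshold
$0.05/(n_{\text{GRS}} \times n_{\text{covariates}})$ (e.g. 5 scores × 17
covariates → $5.88\times10^{-4}$). Both hold their nominal type-I error in
the package's 400-replicate null suites.

## The synthetic cohort generator

`sim_scenario()` + `simulate_cohort()` generate, in order: biallelic
variants with frequencies uniform on an interval and normal per-allele
effects; independent Binomial(2, eaf) dosages (Hardy–Weinberg, linkage
equilibrium — LD is deliberately out of scope); an exposure driven by the
standardized true score, a standard-normal latent confounder $U$ (retained
in the output for oracle checks) and noise; and an event time from a
Weibull law (exponential by default — no baseline hazard is published for
the motivating cohorts, and a constant hazard gives closed-form checks like
the event fraction $1 - e^{-\lambda_0 c}$) whose log hazard is
$\beta_X X + \beta_U U + \sum_j \alpha_j g_j$, the $\alpha_j$ being direct
(pleiotropic) variant effects: zero, balanced (mean 0) or directional.
Censoring is administrative at a configurable horizon (the motivating
cohorts differ, 11.7 vs 20.4 years mean follow-up, so this is a knob)
plus optional uniform loss to follow-up, whose intensity is a free
parameter because no censoring mechanism beyond end-of-follow-up dates is
published. A configurable fraction of participants is flagged prevalent,
independently of covariates — a simplification, since the analyses only
ever exclude them.

Binary exposures use a logistic liability, $\Pr(X=1) =
\text{logit}^{-1}(c_0 + aZ + bU)$ with $c_0 = \text{logit}(\text{prevalence})$
fixing the prevalence at covariate means and $a$ chosen so the score
explains the target share of liability variance — this gives "per doubling
of odds" an exact meaning inside the generator. Continuous exposures set
the score coefficient to $\sqrt{v}$ on the unit-variance scale so the
regression $R^2$ matches the scenario's `variance_explained`.

**Defaults are the study conditions.** n = 20 000 (a desk-scale stand-in
for biobank cohorts), m = 50 instruments, `variance_explained` = 0.006
(the 0.5–0.6% of variance typical for sleep-trait scores), confounder
effects 0.3 (exposure) and 0.2 (log hazard), true HR 1.25 per unit,
baseline hazard 0.002/year with a 12-year horizon (≈ 2.4% cumulative
incidence, matching the ~2.3% incident-AMI fraction of the larger
motivating cohort), no pleiotropy, no prevalent cases. These were chosen
once, from the published scale of each quantity, and are not tuned.

**What passing tests do and do not show.** The generator reproduces the
*assumed* structure: linkage equilibrium, a single well-behaved latent
confounder, exactly proportional hazards, no competing risks,
exposure-independent censoring. Passing calibration under it validates the
estimators' logic and implementation — not robustness to LD between
instruments, time-varying effects, competing risk from death, or selection
into the cohort, none of which the generator emulates.

## Numerical and degenerate-input choices

* Bootstrap and replicate seeds derive from the master seed via a counter
  (stable under changes of iteration count); all derived seeds stay inside
  32-bit integer range.
* Stage-1 logistic separation (fitted probabilities at 0/1 or
  non-convergence) is an error for the point fit and a tallied failure
  inside the bootstrap.
* Median splits send ties low; an all-tied score yields a degenerate
  all-low split with a warning rather than an error.
* The weighted-mode density argmax is bracketed on a 512-point grid and
  refined by golden-section search, so it is reproducible to ~1e-10 and
  comparable against independent dense-grid oracles; an all-equal ratio
  vector short-circuits to that value (the kernel bandwidth would be zero).
* ICD codes are matched by prefix after stripping dots and whitespace and
  upper-casing; empty or missing codes are rejected, never skipped.
* A same-day hospital and death record yield the same event date either
  way, so no source precedence is needed; a diagnosis on the enrolment day
  itself counts as prevalent (the conservative tie-break).
* Monomorphic variants, constant covariates and empty factorial groups are
  surfaced with warnings or errors naming the offender; nothing is dropped
  silently.

## Problem sizes used in validation

The calibration suites run 200 replicates at n = 20 000 with 50 variants
and 200 bootstrap iterations for TSPS recovery and coverage; 200 replicates
of four 5 000-person groups for RERI calibration (additive and
multiplicative); 200 summary-level replicates with 50 variants for
MR-Egger intercept recovery; and 400 null replicates each for the
proportional-hazards and confounder-scan type-I error. These sizes give
Monte-Carlo error comfortably below the tolerances asserted while keeping a
full validation run to a few minutes on one CPU; the same suites back
`scripts/acceptance.R`.

## Known limitations

No LD-aware instrument handling (clumping/pruning is up to the user's
weight file); no competing-risk second stage; no multivariable MR; no
two-stage residual inclusion; the factorial design assumes the two scores
are (near-)independent, which median splits do not fix if they are not.
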