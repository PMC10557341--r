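# sleepmr

One-sample and factorial Mendelian randomization (MR) for censored
time-to-event outcomes, built for studies that ask how sleep traits
(insomnia symptoms, sleep duration, chronotype) causally affect the risk of
incident acute myocardial infarction (AMI) in biobank cohorts — and for
anyone who needs the same machinery for another exposure/outcome pair.

Individual-level biobank data are access-restricted, so the package ships a
synthetic-cohort generator with the exact statistical structure the analysis
assumes (genotypes → exposure → proportional-hazards outcome, with
confounding, pleiotropy, censoring and prevalent cases). Every stage of the
pipeline is validated against that generator and against closed-form or
brute-force oracles.

## What it computes

**Two-stage predictor substitution (TSPS) with a Cox second stage.** A
genetic risk score *G* instruments an exposure *X*. Stage 1 regresses *X* on
*G* and covariates (linear for continuous *X*, logistic for binary *X*),
restricted to participants who did not experience the event; stage 2 fits a
Cox model of the outcome on the stage-1 fitted values (computed for everyone)
plus the same covariates:

> stage 1: E[X | G, C] = a + b·G + c·C (non-cases only)
> stage 2: h(t) = h₀(t) · exp(β·X̂ + d·C)

β is the causal log hazard ratio per exposure unit; for binary exposures it
is rescaled per doubling of the odds by multiplying with ln 2 = 0.693.
Standard errors come from a participant bootstrap that reruns both stages.

**2×2 factorial MR with RERI.** Two risk scores are split at their medians
(ties low); the four genetic-predisposition groups enter a Cox model against
the double-low reference, and additive interaction is measured by the
relative excess risk due to interaction,

> RERI = HR₁₁ − HR₁₀ − HR₀₁ + 1,

with a delta-method CI on the jointly normal log HRs (parametric-bootstrap
CI as a cross-check), computed only when no HR is preventive. A continuous
variant uses both scores per SD plus their product term.

**Supporting modules.** Questionnaire phenotype derivation (insomnia, sleep
duration cut-offs, chronotype), incident/prevalent outcome derivation from
ICD-coded records (ICD-9 410, ICD-10 I21/I22), allele harmonization and
weighted/unweighted score construction with R²/F instrument strength,
summary-statistic sensitivity estimators (IVW, MR-Egger, simple/weighted
median, weighted mode), Schoenfeld-residual proportional-hazards checks and
GRS–confounder scans with Bonferroni flagging, and a YAML-configured
pipeline runner.

## Worked example

```r
library(sleepmr)
library(dplyr)

sc <- sim_scenario(n = 20000, m = 50, variance_explained = 0.02,
                   true_log_hr = log(1.25), baseline_hazard_rate = 0.005,
                   seed = 42)
sim <- simulate_cohort(sc)
grs <- compute_grs(sim$genotypes, sim$variants, mode = "weighted")
cohort <- mutate(sim$cohort, grs = grs$score)

instrument_strength(cohort$exposure, cohort$grs)
#> # A tibble: 1 × 3
#>       r2 f_stat     n
#>    <dbl>  <dbl> <int>
#> 1 0.0195   398. 20000

tsps_cox(cohort, "exposure", "grs", covariates = c("age", "sex"),
         n_boot = 200, seed = 1)
#> <mr_tsps> two-stage predictor substitution Cox estimate
#>   HR 1.059 (95% CI 0.694, 1.617) per exposure unit
#>   n = 20000, events = 1222, bootstrap n = 200 (seed 1, 0 failed)
```

The instrument explains ~2% of exposure variance (F ≈ 398, far from the
weak-instrument zone). The causal HR estimate is 1.06 with a 95% bootstrap
CI of 0.69–1.62: one realization under a true HR of 1.25 per exposure unit —
the interval covers the truth, and its width is what a score of this
strength buys at ~1200 events. Factorial MR on two half-score instruments
from the same cohort:

```r
grsA <- compute_grs(sim$genotypes, sim$variants[1:25, ], mode = "weighted")$score
grsB <- compute_grs(sim$genotypes, sim$variants[26:50, ], mode = "weighted")$score
factorial_mr(cohort, grsA, grsB, covariates = c("age", "sex"), force = TRUE)
#> <mr_factorial> 2x2 factorial MR Cox fit
#> # A tibble: 3 × 8
#>   group         n events estimate std.error    hr conf.low conf.high
#>   <chr>     <int>  <int>    <dbl>     <dbl> <dbl>    <dbl>     <dbl>
#> 1 a_high     4939    312  0.0568     0.0807  1.06    0.903      1.24
#> 2 b_high     4939    303  0.0210     0.0811  1.02    0.871      1.20
#> 3 both_high  5061    304  0.00402    0.0813  1.00    0.856      1.18
#> RERI -0.076 (95% CI -0.309, 0.158)
```

The four groups are near 25% each (median splits of two near-independent
scores), every group HR is close to 1 (each half-score carries only half the
exposure signal, diluted across the median split), and the RERI interval
comfortably includes 0 — no additive interaction, as built. All fitted
objects support `tidy()`, `glance()` and (for factorial fits) `autoplot()`;
`run_pipeline()` drives the whole chain from a YAML config and writes
seed-stamped CSV tables.

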