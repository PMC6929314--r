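---
title: "Methods: marginal structural estimation on claims-style wave panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marginal structural estimation on claims-style wave panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`msmwave` estimates the population-average (marginal) causal effect of a
time-varying binary exposure — being in the low-income group — on two
claims-coded health outcomes: preventable hospitalization (an inpatient stay
whose primary diagnosis belongs to an ambulatory-care-sensitive-condition
list) and comorbidity burden (an Elixhauser-style category count). The
methodological difficulty is *treatment-confounder feedback*: health burden
raises utilization and depresses income, prior low income further erodes
health, and both paths touch later exposure and later outcomes. Conditioning
on such a time-varying covariate in an ordinary regression simultaneously
blocks part of the causal effect (the covariate is a mediator of past
exposure) and opens collider paths; omitting it leaves confounding. Marginal
structural models resolve this by *weighting* instead of conditioning.

## Estimation

**Stage 1 — stabilized weights.** For each wave $t$, per-wave logistic
models estimate the probability of the observed exposure level. The
stabilized treatment weight is the telescoping product

$$SW(t)=\prod_{k=1}^{t}\frac{\Pr\{A(k)\mid \bar A(k-1), L(0)\}}{\Pr\{A(k)\mid \bar A(k-1), \bar L(k)\}},$$

with baseline covariates $L(0)$ in the numerator and the time-varying
history $\bar L(k)$ added in the denominator. Loss to follow-up is handled by
inverse-probability-of-censoring weights estimated with discrete-time
per-interval logistic models (the numerator on baseline covariates and
exposure history, the denominator adding the time-varying covariates); with
multi-year intervals only interval survival probabilities enter the weights,
so the discrete form is an exact, reproducible substitute for a
continuous-time hazard fit. The total weight is $SW(t)\times CW(t)$,
truncated at 50 (weights above the cap are considered extreme and set to the
cap). Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ before ratios are
formed; clip and truncation counts are reported in the weight diagnostics.

**Stage 2 — weighted outcome models.** A pooled subject-wave regression of
the outcome on current exposure $A(t)$, the baseline covariates used in the
weight numerator (required for the validity of stabilized weights), and wave
indicators, weighted by the truncated total weight: logistic link for the
binary outcomes, identity link for the continuous comorbidity index. The
default uncertainty is a subject-clustered sandwich; the headline interval
is the cluster bootstrap (`confidence_interval(..., "cluster_bootstrap")`),
which resamples subjects and re-estimates the weights inside every
replicate. The sandwich option is documented as anti-conservative because it
treats the weights as known.

**Covariate handling.** Continuous covariates are aggregated by the interval
mean over each wave year and the two preceding years; categorical covariates
by the interval mode, with ties broken in favour of the most recent year
(the tie rule is a package decision — the source convention is unstated —
chosen to favour current status). Income groups use the cumulative average
income from 2001 up to the year before each wave (the 2009 wave uses
2001–2008), dichotomized at the within-wave 25th percentile of uncensored
subjects with strict `<` membership against the type-7 empirical quantile.
Utilization counts enter model matrices as `log1p`, incomes as `log`.

**Positivity and the income rule.** Because exposure is a deterministic
function of cumulative income, the denominator model must not condition on
the cumulative income itself (the probability would be degenerate) nor on
its lag: experimentation during development showed that the lagged
cumulative income drives fitted probabilities onto the boundary and
destabilizes the weights (mean stabilized weight drifting to 5 at later
waves) — a practical positivity violation. The denominator therefore
conditions on the baseline covariates, the previous exposure group, the
current wave's aggregated covariates, and the previous wave's utilization,
which capture the confounder history without degeneracy.

**Balance diagnostics and what they can show.** `balance_table()` reports
absolute standardized mean differences unweighted and weighted. The weighted
column uses the *unstabilized* truncated weight (the product of inverse
denominator probabilities): that is the weight under which measured
covariates should be marginally independent of exposure. Stabilized weights
with covariates in the numerator *deliberately* preserve the association
between exposure and the numerator covariates (the baseline income group
alone has an SMD near 1 in any weighted sample), so they are the wrong
yardstick for balance even though they are the right weights for estimation.
On panels with healthy positivity (the packaged discrete worlds), weighting
drives the worst SMD from ~0.6 to under 0.01. On the claims world, exposure
persistence makes late-wave propensities extreme: weighting removes most of
the first-wave imbalance (1.06 to 0.20) but residual imbalance remains at
later waves. This is a diagnostic of practical positivity, not an estimator
defect — effect recovery is unaffected because estimation combines
stabilized weights with baseline adjustment — and it is surfaced rather than
hidden.

## Clinical coding rules

A comorbidity category counts toward the index only when validated by at
least two ambulatory encounters or one inpatient encounter carrying one of
the category's codes within the lookback window (the wave's 3-year
aggregation window; assessment years are the wave year plus one for the
outcome and the wave year itself for the covariate). The rule is applied
*per category*: it exists to validate each claimed condition, so two single
mentions of different conditions validate neither. The index is reported
raw, as a positivity flag, and in the conventional 3-level binning (0, 1–3,
≥4). Preventable hospitalization requires the ACSC code in *primary*
position on an inpatient record; secondary-position codes never qualify.
Code sets are configurable plain-text files; the bundled sets are small
ICD-10-style toys (11 ACSC codes, 6 comorbidity categories), deliberately
not the full AHRQ/Elixhauser catalogs.

## The synthetic world

The generator stands in for a closed national claims database; it emulates a
17-year cohort (baseline 2000, exposure waves 2003–2015, outcome years
2004–2016) with the causal structure the estimator is designed for, not the
epidemiology of any real population:

* latent health burden $U(t)$: AR(1) (coefficient 0.5, stationary SD 1) with
  feedback $\gamma A(t-1)$;
* outpatient visits $\sim$ Poisson$(\exp(2.3 + 0.8\,U))$ and inpatient stays
  $\sim$ Poisson$(\exp(-2.2 + 0.5\,U))$ per year — the measurable proxies of
  $U$; the 0.8 loading makes the 3-year visit average an accurate proxy, so
  measured-confounder adjustment is achievable by design;
* yearly income: lognormal with secular growth, occupation and residence
  shifts, and $-\alpha\,U(t)$, so low income marks high burden
  ($\alpha = 0.5$ in the headline config); exposure is *derived* from income
  through the same cumulative-percentile rule the panel builder uses, and
  the generated panel reproduces the generator's internal exposure, outcome,
  and comorbidity states exactly (tested);
* outcomes: wave hospitalization $\text{logit}^{-1}(-3.6 + \beta A + 0.4 U +
  \text{age}, \text{sex terms})$ (≈3–4% per wave); six chronic comorbidity
  categories with onset hazards depending on $A$, $U$, and age, and 0.85
  persistence between assessments;
* censoring: per-interval logistic hazard with exposure (+0.2) and burden
  (+0.2) effects, death the dominant recorded reason, intercept calibrated
  so overall attrition is 10.8% over the five intervals;
* encounters: validated comorbidity emissions (two ambulatory visits or one
  admission), ACSC admissions for hospitalization events, plus
  *non-qualifying* distractors (secondary-position ACSC codes, single
  ambulatory comorbidity mentions) and unrelated noise encounters, so the
  coding rules are exercised, not just satisfied.

Baseline distributions (residence 59/31/10, six occupation categories with
strong income gradients, ages 20–79) echo the published descriptive tables
at face-value level only. What the generator does *not* emulate: real ICD
code epidemiology, economy-wide income dynamics, measurement error in
diagnoses, or unmeasured confounding. A green recovery test therefore
establishes that the estimator recovers a known truth *when its assumptions
hold*, nothing more.

**Calibration.** The headline config (`paper_like_config()`) is calibrated
by root-finding on the counterfactual simulator `true_marginal_effect()`
(common random numbers across arms, so the objective is smooth and the
result deterministic): the direct exposure effects are set so the true
marginal odds ratios are 1.28 (hospitalization) and 1.04 (comorbidity
positivity), and the censoring intercept so attrition is 10.8%. The frozen
constants are `beta_exposure = 0.120391`, `beta_comorbidity = 0.012574`,
`censor_rate = 0.017391`. Note the calibrated *marginal* contrast includes
the feedback pathway ($A \to U \to Y$), so the direct coefficients are
smaller than $\log$ of the target odds ratios.

## Validation design

* **Exact recovery**: the wave panel rebuilt from the emitted claims tables
  must match the generator's internal exposure/outcome states bit for bit.
* **g-formula oracle**: on three packaged discrete worlds (≤3 waves, binary
  states, logistic conditionals) counterfactual regime probabilities are
  computed by exhaustive trajectory enumeration and compared with the
  IPTW pipeline on samples of $10^5$ (agreement within 0.01).
* **Parameter recovery**: on the calibrated world at $n = 50{,}000$ the
  end-to-end estimate averaged over 20 seeds must lie within ±0.05 of 1.28,
  and the time-varying-adjusted naive estimator must be farther from the
  truth in at least 16 of 20 seeds.
* **Coverage**: 95% cluster-bootstrap intervals on null worlds cover 1.0 at
  the nominal rate (90–99 of 100 seeded replicates at reduced size).

## Numerical choices and degenerate inputs

Quantile convention: type 7 (linear interpolation) everywhere, strict `<`
for low-income membership; all-identical incomes label everyone high-income
with a warning. Aliased (collinear) design columns are dropped and the model
refit rather than erroring — the first wave's lagged exposure duplicates the
baseline income group by construction. Censoring intervals with no events
contribute ratio 1; a panel with no censoring at all yields unit censoring
weights with a warning. The first censoring interval's numerator and
denominator share one (baseline-only) design, so its ratio is exactly 1 and
is not fitted. Weight truncation is inclusive at the cap. The three-subject
hand fixture in the test suite traces every aggregation, grouping, coding,
and censoring rule against a by-hand computation.

## Known limitations

Single-stream vectorised generation: cohorts are bit-reproducible for a
given seed, but there is no per-subject stream, so generating a cohort in
parallel shards is unsupported (parallel execution is out of scope). The
bootstrap uses a cached-design fast path verified against the public
pipeline on an identity resample; it re-estimates weights but not the wave
panel itself (aggregation and income grouping are deterministic given the
resampled subjects' data, but the within-wave income percentile is treated
as fixed — at the cohort sizes used its sampling noise is negligible
relative to the outcome-model noise). The continuous-time (proportional
hazards) censoring formulation is an extension point, not implemented.
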