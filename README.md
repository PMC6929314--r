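# msmwave

Marginal structural models (MSM) for longitudinal claims panels: estimating
the causal effect of a time-varying binary exposure — low income — on
claims-coded health outcomes (preventable hospitalization, Elixhauser-style
comorbidity) in the presence of treatment-confounder feedback and
informative loss to follow-up.

The package is aimed at epidemiologists and health-services researchers who
work with claims-like longitudinal records (one row per subject-year plus
encounter-level diagnosis codes) and need the full two-stage MSM workflow as
tested, reusable components rather than one-off scripts. Because the data
this design targets are typically closed registries, the package ships a
synthetic cohort generator with *known* causal structure, plus an exact
g-formula oracle, so every stage of the pipeline is validated by parameter
recovery against ground truth.

## The model

For waves $t = 1,\dots,T$, exposure $A(t) \in \{0,1\}$ (low income: below
the within-wave 25th percentile of cumulative average income), baseline
covariates $L(0)$, and time-varying covariates $\bar L(t)$ (interval-mean
utilization, interval-mode residence and occupation, comorbidity category),
the stabilized inverse-probability-of-treatment weight is

$$SW(t)=\prod_{k=1}^{t}\frac{\Pr\{A(k)\mid \bar A(k-1), L(0)\}}{\Pr\{A(k)\mid \bar A(k-1), \bar L(k)\}},$$

multiplied by an inverse-probability-of-censoring weight (discrete-time
per-interval models) and truncated at 50. The causal odds ratio is then
recovered by a weighted pooled logistic regression of the wave outcome on
current exposure, baseline covariates, and wave indicators, with
subject-clustered uncertainty (sandwich default, cluster bootstrap with
weight re-estimation as the headline interval).

## Worked example

```r
library(msmwave)

cfg     <- paper_like_config(n_subjects = 20000, seed = 7)
cohort  <- generate_cohort(cfg)        # claims-style tables
panel   <- build_wave_panel(cohort)    # subject x wave analysis panel
weights <- compute_weights(panel)      # SW(t) x censoring weight, truncated
fit_msm(panel, weights)                # weighted pooled outcome model
true_marginal_effect(cfg, 2e5)         # counterfactual ground truth
```

Output from this exact run:

```
<weight_set> 93919 rows; mean sw 0.997; mean total 0.997; truncated 10 (0.01%) at cap 50
<msm_result> outcome: preventable_hospitalization (robust_sandwich)
  odds ratio 1.3741 (95% CI 1.1607-1.6266); log-OR 0.3178 (se 0.0861)
  19610 subjects, 93919 subject-wave rows, ESS 37807.5
true marginal OR: 1.281
```

Reading this: the mean stabilized weight per row is ~1 (a correctness
diagnostic — stabilized weights average to one under well-specified
models), almost nothing is truncated, and the weighted estimate (1.37, CI
1.16–1.63) brackets the world's true marginal odds ratio of 1.28, which the
generator was calibrated to by root-finding on the counterfactual
simulator. A naive pooled regression adjusted for the time-varying
covariates on the same panel
(`naive_estimate(panel, adjustment = "baseline_timevarying")`) gives
1.20 — biased toward the null because
conditioning on a covariate affected by prior exposure blocks part of the
effect; that contrast is the point of the method.

The pipeline is also scriptable end to end:

```r
run_pipeline(list(out_dir = "run1",
                  sim = list(n_subjects = 20000, seed = 7),
                  estimation = list(seed = 7)))
```

or from the shell via the CLI
(`Rscript $(Rscript -e 'cat(system.file("cli/msmwave.R", package="msmwave"))') simulate --n_subjects 5000 --out cohort/`)
with subcommands `simulate`, `validate`, `build-panel`, `weights`,
`balance`, `estimate`, `run`.

## Package layout

| module | contents |
| --- | --- |
| `sim_config` / `generate_cohort` / `true_marginal_effect` | synthetic claims cohorts with feedback, confounding, informative censoring; counterfactual truth |
| `wave_spec` / `build_wave_panel` / `summarize_wave` | interval aggregation, cumulative-income exposure groups, eligibility and censoring flags, descriptive tables |
| `code_sets` / `compute_eci` / `flag_preventable_hospitalization` | claims coding: validated comorbidity index, ACSC primary-diagnosis flags |
| `fit_exposure_models` / `compute_stabilized_weights` / `fit_censoring_models` / `combine_and_truncate` | the weight engine |
| `standardized_mean_difference` / `balance_table` | balance diagnostics |
| `fit_msm` / `naive_estimate` / `confidence_interval` | weighted outcome models, comparators, cluster bootstrap |
| `discrete_world` / `gformula_regime_probability` / `sample_world` | exact enumeration oracle |
| `run_pipeline` / `validate_cohort` / `msmwave_cli` | orchestration |

See `vignettes/msmwave-methods.Rmd` for the model, the generator's stated
world, numerical choices, and known limitations.
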