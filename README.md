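# mpapk

Population pharmacokinetics and limited sampling strategies for
mycophenolic acid (MPA) in adult heart-transplant recipients.

MPA exposure over one twice-daily dosing interval (AUC<sub>0–12h</sub>)
predicts graft rejection, but measuring it directly takes ten timed blood
samples. `mpapk` implements a published two-compartment population model
with first-order lagged absorption for this population — fixed
bioavailability F = 0.95, covariate effects of proton-pump-inhibitor (PPI)
co-medication on F (×0.724), estimated glomerular filtration rate on
apparent clearance (CL/F = 7.36 · (1 + (eGFR − 57) · 0.00791) L/h) and
albumin on the central volume (V₂/F = 5.69 · (ALB/40)<sup>−7.31</sup> L),
lognormal between-subject variability and combined residual error — and
the estimation strategies built on it:

* **simulation** of steady-state exposure under covariate scenarios and of
  whole virtual cohorts (`scenario_table()`, `generate_cohort()`,
  `simulate_cohort_profiles()`);
* **MAP Bayesian estimation** of individual parameters and
  AUC<sub>0–12h</sub> from sparse samples (`map_fit()`, `auc_from_map()`);
* **limited-sampling design**: an expected-information (ED-type) search
  over sparse designs (`optimize_design()`, `evaluate_design_auc()`) and
  stepwise multilinear AUC regression including the published four-point
  equation (`stepwise_mlr()`, `published_equation()`, `apply_mlr()`);
* **agreement and adequacy diagnostics**: %ME/%RMSE, Passing–Bablok,
  Bland–Altman, normalized prediction distribution errors, and
  prediction-corrected visual predictive checks;
* a reduced-scale **population fitter** (subject-level Laplace marginal
  likelihood) with stepwise covariate selection and a subject bootstrap,
  for recovery studies on simulated cohorts.

Everything is seeded and reproducible; no clinical data ship with the
package. See the vignette in `vignettes/mpa-exposure-methods.Rmd` for the
model, the design decisions and their rationale.

## Worked example

Steady-state exposure of a population-predicted patient with normal renal
function (eGFR 90), albumin 40 g/L, no PPI, on 500 mg twice daily — then
the same AUC recovered by MAP from three samples, and by the published
equation:

```r
library(mpapk)

pop <- mpa_params()                      # published population estimates
cov <- covariate_profile(egfr = 90, alb = 40, ppi = 0)
reg <- regimen(dose = 500, tau = 12)

ind <- apply_covariates(pop, cov)
auc_analytic_ss(ind, reg)
#> [1] 51.17883

tab <- scenario_table(pop)               # all 24 covariate scenarios
tab[tab$egfr == 90 & tab$alb == 40, ]
#>    ppi alb egfr      auc auc_report
#> 7    0  40   90 51.39184       51.4
#> 19   1  40   90 37.20769       37.2

# a virtual patient, sampled at the sparse design {0, 1, 4} h
subject <- sample_individual(pop, cov, seed = 42)
conc <- concentration(subject, reg, c(0, 1, 4))
fit <- map_fit(observation_set(c(0, 1, 4), conc, cov, reg), pop)
fit$auc_ipred                            # MAP estimate of AUC_0-12h
#> [1] 84.70029
auc_analytic_ss(subject, reg)            # this subject's true exposure
#> [1] 90.19987

# the published four-point equation at its fixed times
apply_mlr(published_equation(),
          c("0" = 2.1, "0.5" = 6.0, "1" = 8.4, "4.5" = 3.2))
#> [1] 42.1651
```

The scenario table reads: with normal renal function this regimen yields
an exposure of about 51 mg·h/L, which PPI co-medication cuts to 37 mg·h/L —
at the edge of the efficacy target of 36 mg·h/L. The MAP estimate (84.7)
recovers the virtual subject's true AUC (90.2) from three samples to
within the accuracy expected of sparse sampling under this model's
variability.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "mpapk", package = "mpapk")`, with subcommands
`simulate-scenarios`, `cohort-generate`, `estimate-auc`, `mlr-auc`,
`mlr-fit`, `design-optimize`, `evaluate` and `pop-fit`; stochastic
subcommands require an explicit `--seed` and every run writes a
provenance block.

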