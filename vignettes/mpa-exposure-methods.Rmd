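---
title: "Estimating mycophenolic acid exposure: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mycophenolic acid exposure: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpapk)
```

## The problem

Mycophenolic acid (MPA), the active metabolite of mycophenolate mofetil
(MMF), is dosed twice daily in heart-transplant recipients. Exposure over
one dosing interval — the area under the concentration-time curve,
AUC~0–12h~ — predicts rejection risk (values below about 36 mg·h/L are
considered insufficient), but measuring it directly needs ten or more
blood samples. `mpapk` packages a published population pharmacokinetic
(PPK) model for this population together with the two practical estimation
routes built on it: maximum a posteriori (MAP) Bayesian estimation from a
few samples, and a fixed-timepoint multilinear equation.

## Structural and statistical model

Disposition follows a two-compartment model with first-order absorption,
an absorption lag, and first-order elimination, parameterized by the
apparent oral parameters CL/F, V~2~/F, Q/F, V~3~/F plus Ka and T~lag~, and
a fixed bioavailability F = 0.95. The concentration is evaluated in closed
form (a lagged triexponential; at steady state each exponential term is
divided by $1 - e^{-\lambda\tau}$), which the test suite verifies against
adaptive-step numerical integration to below 10^-5^ relative error.

Three covariate effects enter the typical values:

* PPI co-medication multiplies F by 0.724 (a 27.6% reduction);
* eGFR enters clearance linearly,
  $CL = CL_{tv}\,(1 + (eGFR - 57)\cdot 0.00791)$;
* albumin enters the central volume as a power,
  $V_2 = V_{2,tv}\,(ALB/40)^{-7.31}$.

Between-subject variability is lognormal per parameter
($P_i = P_{tv} e^{\eta_i}$) with a diagonal covariance. The source model
estimated a full covariance matrix but published no correlations, so the
diagonal is the only faithful reconstruction; the consequences are
discussed under *Limitations*. Reported percent coefficients of variation
are mapped to $\omega$ as CV/100 by default; the exact lognormal reading
$\omega^2 = \ln(1 + CV^2)$ is available as
`mpa_params(iiv_transform = "lognormal_exact")`. The two differ materially
only for the two volumes, whose CVs approach 190%. Residual error combines
a 26.1% proportional and a 0.144 mg/L additive component.

Units are milligrams of MMF and mg/L of MPA throughout. The published
steady-state exposure table is reproduced on this scale directly
(AUC = F·D/CL up to trapezoid discretization), so no molar conversion is
applied anywhere.

## Exposure simulation

`scenario_table()` evaluates the population-predicted ($\eta = 0$)
steady-state profile at 500 mg bid on a half-hour grid with both endpoints
included (25 points over 12 h) and integrates by the linear trapezoid;
this grid convention reproduces the published 24-scenario table to within
one rounding unit at albumin 30–40 g/L and within 0.4% everywhere.
Reported values are rounded to one decimal, half away from zero. The
half-hour trapezoid sits up to ~5% above the analytic F·D/CL in the
albumin-60 scenarios, where the fitted albumin exponent collapses the
central volume to ~0.3 L and the absorption peak becomes very sharp; this
is a property of the published table's own grid, not an error, and the
package reports the unrounded trapezoid next to the rounded value.

## MAP Bayesian estimation

For a subject with sparse concentrations, `map_fit()` minimizes

$$\sum_j \frac{(y_j - f_j(\eta))^2}{g_j^2} \;+\; \eta^\top \Omega^{-1} \eta$$

over the random effects, with BFGS from five deterministic starts (the
prior mode and four $\pm0.5\omega$ patterns; ties break to the smallest
objective, then lexicographically). Below-quantification records are
excluded, mirroring the source analysis, which dropped its single such
sample. The AUC is then the half-hour trapezoid of the fitted steady-state
profile.

The weights $g_j$ are a genuine design choice. The exact posterior mode
(extended least squares, ELS) uses $g(f)$ and carries a $\ln g^2$ term;
with a 26% proportional component that term *rewards under-prediction* by
roughly $\sigma_{prop}^2 \approx 7\%$ in relative terms, a bias that
persists no matter how dense the data are. Because the published
evaluation of this workflow reports essentially unbiased AUC recovery, the
package anchors the weights at the observations, $g(y)$, and drops the
then-constant log term. The ELS form remains available
(`map_control(objective = "els")`) and is used, untruncated, inside the
population marginal likelihood where it is not an approximation but the
density itself. Convergence is declared at a scaled gradient norm below
10^-3^ — the practical noise floor of finite-difference gradients here;
fitted AUCs reproduce across platforms to much better than 0.1%.

## Limited sampling design

`linearized_fim()` builds the first-order population Fisher information at
a candidate design: sensitivities of the population prediction to the nine
estimable fixed effects, a prediction covariance from the linearized
random effects plus residual variance, and the Gaussian trace formula for
the nine variance components. A three- or four-point design cannot inform
all eighteen parameters, so raw log-determinants are $-\infty$ and
pseudo-determinants of different ranks are not comparable. The expected
(ED-type) criterion therefore regularizes on the relative scale:

$$\phi(\xi) = \mathbb{E}_{\mathrm{cov}}\left[\log\det\!\big(I + D\,F(\xi)\,D\big)\right],$$

with $D$ the diagonal of parameter magnitudes — equivalently, a unit
lognormal prior precision per parameter — and the expectation taken by
Monte Carlo (default 30 draws, seeded) over the virtual-cohort covariate
distribution. This criterion is finite, permutation-invariant and
monotone under added samples. `optimize_design()` enumerates all
multisets of up to four times on the 0–6 h half-hour grid with the
pre-dose sample forced (560 designs) and returns the argmax; replicate
support points are allowed and reported as unique times.

Under this criterion the winning support is {0, 0.5, 1, 2.5} h rather than
the published {0, 1, 4} h: with a 186% CV on the central volume, early
samples carry large information about the volume parameters. The package
reports both the winner and the criterion of any design, so the published
support can be compared directly; its MAP accuracy is what
`evaluate_design_auc()` measures.

`stepwise_mlr()` performs forward selection of timepoint concentrations by
adjusted r² with an entry p of 0.05, backward removal at 0.10 (the source
states only "stepwise"; these are the conventional thresholds), a
four-term cap, a 6-h window, a variance-inflation-factor screen at 10, and
an intercept retained only when significant at 0.05. The published
four-point equation ships verbatim as `published_equation()`.

## Diagnostics

`npde()` simulates replicate observation vectors per subject, decorrelates
observed and simulated vectors by the inverse Cholesky factor of the
empirical simulation covariance, and maps ranks through the normal
quantile function, clamping at $1/(2n_{sim})$. `pcvpc()`
prediction-corrects within bins placed midway between the intensive
schedule times. `passing_bablok()` implements the original 1983 rank
procedure (slopes of −1 discarded, offset by the count below −1) without
confidence intervals; `bland_altman()` uses raw differences and 1.96
sample standard deviations. On self-simulated data (50 subjects, 1,000
replicates) the NPDE mean and variance sit within 0.05 and 0.15 of their
nominal 0 and 1.

## Population refitting

`marginal_ofv()` approximates −2 log marginal likelihood subject-by-subject
by the Laplace method at each conditional mode. The 7-dimensional
conditional posteriors are multimodal under the very wide volume priors,
so during population fitting every subject's mode is solved the same way —
a single quasi-Newton run from the prior mode — keeping the outer
objective a deterministic, internally consistent function of the
parameters; mixing inner solves of different quality would inject offsets
larger than any outer gradient signal. Even so, parameter changes can
snap individual subjects between posterior basins, leaving small
discontinuities in the surface that trap simplex and gradient optimizers
in shallow pockets. `fit_population()` therefore defaults to cyclic
coordinate descent on log-transformed positive parameters with shrinking
7-point search brackets (three-fold down to a few percent around the
current value): each line search is global over its bracket, so the kinks
cannot capture it. Nelder-Mead remains available as
`method = "simplex"`. This is a
deliberate approximation for recovery studies on simulated cohorts — not
a re-implementation of the original estimator — and the absorption lag is
bounded at 1.5 h during fitting because lags crossing sample times create
objective discontinuities. Stepwise covariate selection uses the ΔOFV
thresholds 6.63 (inclusion, p < 0.01) and 10.83 (retention, p < 0.001)
over the three structural effects the parameterization supports
(PPI→F, eGFR→CL, ALB→V~2~). The bootstrap resamples subjects with a desk
default of 100 replicates.

The recovery study shipped in the tests simulates 91 subjects (14
intensive, 77 sparse, residual noise on) and refits CL/F, V~2~/F and the
eGFR slope with the variance components held at their generating values —
a problem size chosen so the whole suite runs on a single CPU in minutes
while still exercising mixed schedules at the original cohort size.

## The synthetic cohort

`generate_cohort()` emulates the study population: PPI prevalence 0.495;
eGFR lognormal with median 57.2 mL/min/1.73 m², log-sd 0.55, truncated to
the observed 6.3–197.1 range (the source prints only median and range;
the log-sd was chosen once so that a cohort of ~100 plausibly spans that
range); albumin normal (40.5, 5) g/L truncated to 25–60; doses 250/500/750
mg with 500 modal. Covariates are drawn independently — no eGFR–albumin
correlation is published. It does not emulate enterohepatic recirculation
(secondary peaks), assay bias, time-varying covariates, or dropout;
passing tests therefore demonstrate internal consistency of the workflow
under the stated model, not robustness to those real-data features.

## Known limitations

* **Diagonal Ω.** The published between-subject correlations are
  unavailable. Under the diagonal reconstruction with the full published
  CVs, virtual subjects are more heterogeneous than the source cohort
  plausibly was: even an in-sample-optimal linear predictor of AUC from
  the three concentrations at {0, 1, 4} h has a ~4% RMSE floor, and the
  MAP route achieves ~7–9%, against a published 2.9%. The package reports
  what it computes; closing that gap would require the unpublished
  covariance structure.
* The ED criterion's regularization and the FIM linearization are
  first-order; they rank designs, they do not promise estimator variances.
* The Laplace population fitter is not the original estimation algorithm
  and is validated only for recovery on simulated data.
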