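---
title: "Methods: population PK and exposure-response for once-daily doravirine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK and exposure-response for once-daily doravirine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

dorapop implements an end-to-end population pharmacokinetic (PK) and
exposure-response workflow for doravirine dosed 100 mg once daily in an
antiretroviral switch setting: a structural PK model with covariates,
nonlinear mixed-effects estimation, empirical-Bayes (post hoc) individual
parameters, steady-state exposure metrics, and binary week-48 virologic
exposure-response analysis. Because the underlying clinical data are
access-restricted, the package ships a seeded trial generator that emulates
the design of a 443-subject immediate-switch cohort with sparse PK sampling;
every statistical claim the package makes is validated against that
generator's known truth or against independent numerical oracles in the test
suite.

## Structural model

Concentrations follow a one-compartment model with first-order absorption
and linear apparent elimination. At steady state under repeated dosing every
$\tau$ hours,

$$C_{ss}(t) = \frac{D\,k_a}{V/F\,(k_a - k_e)}\left[
  \frac{e^{-k_e t}}{1-e^{-k_e\tau}} - \frac{e^{-k_a t}}{1-e^{-k_a\tau}}
\right],\qquad k_e = \frac{CL/F}{V/F},$$

for $t$ hours after a dose. Bioavailability $F$ is not separately
identifiable from oral data alone and is absorbed into the apparent
parameters $CL/F$ and $V/F$ throughout. Doses are stored in nmol
($D = \mathrm{mg}/\mathrm{MW}\times 10^6$, MW 425.75 g/mol by default) and
volumes in litres, so concentrations emerge in nM and the dosing-interval
AUC in nM·h (reported as µM·h).

When $k_a \to k_e$ the two-exponential form degenerates; at relative
difference below $10^{-8}$ the implementation switches to the exact limit
$C_{ss}(t) = \frac{D k}{V}e^{-kt}\left[\frac{t}{1-r} +
\frac{\tau r}{(1-r)^2}\right]$, $r = e^{-k\tau}$, rather than perturbing
the rates. Exposure metrics use closed forms: $AUC_{0-24} = D/(CL/F)$, the
analytic $t_{max}$, $C_{max} = C_{ss}(t_{max})$ and the trough
$C_{24} = C_{ss}(\tau)$. The tests verify the closed-form curve against
brute-force superposition of hundreds of single doses (relative error
$<10^{-6}$) and the AUC identity against trapezoidal integration on a
$10^5$-point grid.

## Covariate submodel

The covariate structure follows the standard pharmacometric
parameterisation: body weight and infection status act on apparent volume,
age on apparent clearance,

$$CL/F = TVCL\cdot(\mathrm{age}/45)^{\beta_{age}},\qquad
V/F = TVV\cdot(\mathrm{wt}/70)^{\beta_{wt}}\cdot\beta_{hiv}^{[\mathrm{HIV}]},
\qquad k_a = TVKA.$$

The exact published coefficient values for doravirine are not publicly
available, so the forms are fixed but every coefficient is configurable and
estimated from the data by default. The healthy-vs-HIV factor is only
estimable when both statuses appear in a dataset; in an all-HIV switch
cohort it is held fixed (default 1) and documented as such. Reference
weight is 70 kg; reference age 45 years, the generator's median.

## Mixed-effects estimation

Between-subject variability is log-normal on $CL/F$, $V/F$ and $k_a$
($\eta_i \sim N(0, \Omega)$ with diagonal $\Omega$), and residual error is
proportional with an optional additive component,
$\mathrm{sd}(y_{ij}) = \sqrt{\sigma_{add}^2 + (\sigma_{prop}
f_{ij})^2}$. The marginal likelihood integrates each subject's $\eta_i$ out
by a Laplace approximation at the conditional mode $\hat\eta_i$ — the
deterministic relative of first-order conditional estimation, chosen here
because it is testable against numerical quadrature:

$$-2\log L_i \approx 2 g_i(\hat\eta_i) - d\log 2\pi + \log\det H_i,$$

with $g_i$ the negative joint log-density and $H_i$ its curvature at the
mode. The inner mode search is a damped Newton iteration run *vectorised
across all subjects simultaneously* (central finite differences of the
closed-form model; trust-region step cap of 2 on each $\eta$ component;
step-halving line search), converging to a gradient norm of $10^{-8}$.
Random effects with $\omega^2 = 0$ are excluded from the integral, so the
all-zero-variance case reduces exactly to the residual log-likelihood at
the typical values. The test suite holds the Laplace value within 1% of a
9-node adaptive Gauss-Hermite quadrature oracle on small instances.

The outer problem maximises this marginal likelihood over
$(\log TVCL, \log TVV, \log TVKA, \beta_{wt}, \log\beta_{hiv}, \beta_{age},
\log\omega^2_{\cdot}, \log\sigma_{\cdot})$ with `nlminb` (relative
objective tolerance $10^{-8}$, warm-starting the inner modes between
evaluations). Because the objective carries a little finite-difference
noise, a run that stops with a "false convergence" code is restarted once
from its solution; if the restart cannot improve the objective beyond
noise level the fit is declared converged. Standard errors invert a central
finite-difference Hessian of $-2\log L/2$ on the transformed scale and map
to the reporting scale by the delta method; a non-positive-definite Hessian
is reported as SEs unavailable together with the condition number.

Post hoc (empirical-Bayes) parameters re-run the inner mode search at the
final estimates; individual parameters are $\text{typical}\times e^{\hat\eta}$.
Subjects with no usable observations sit at the prior mode (typical values)
and are flagged. Shrinkage is reported as
$(1 - \mathrm{SD}(\hat\eta_k)/\omega_k)\times 100\%$.

## Exposure-response analysis

Week-48 binary endpoints use two rules at thresholds of 40 and 50
copies/ml: the regulatory *snapshot* rule (missing = failure, nobody
excluded) and the *observed failure* rule (monotone missingness after
discontinuation for lack of efficacy = failure; missingness for other
reasons = excluded). Missing values without any discontinuation record are
intermittent missingness, for which the observed-failure rule defines no
outcome; they are excluded with a warning.

The exposure-effect model is a maximum-likelihood logistic regression,
$\mathrm{logit}\,P(\text{response}) = \alpha + \beta\,g(x)$, with
$g$ the identity ("linear", exposure in its natural units) or the natural
log. The "linear" label follows the field's usage for a model linear in
exposure on the logit scale; a linear-probability variant (identity link)
is available behind the `link` argument for sensitivity analysis. Slope
inference is Wald by default ($\hat\beta \pm 1.96\,SE$, two-sided p), with
a likelihood-ratio p-value as an option; the published analyses do not name
the test, and the two agree closely away from separation. Complete
separation (e.g. an all-responder dataset) is detected and flagged; no
Wald inference is reported in that case. Linear and log fits on the same
analysis set are compared by AIC, ties resolved to the linear form.

Observed-response summaries split the analysis set at the 25th/50th/75th
exposure percentiles (linear-interpolation quantiles, type 7; boundary ties
fall to the lower quartile) with exact Clopper-Pearson 95% intervals per
quartile. Model predictions carry a delta-method 95% band on the linear
predictor, inverse-logit transformed, evaluated across the 5th-95th
percentile exposure range; grid points outside the data support are flagged
as extrapolation rather than refused.

## The trial generator

`simulate_trial()` emulates a 443-subject immediate-switch cohort, 100 mg
once daily: all subjects HIV-positive and virologically suppressed; weight
log-normal (median 74 kg, 20% CV); age truncated normal (45 ± 11 years on
18-78); sparse sampling at day 1 (predose), week 4 (predose trough),
week 12 (uniform anywhere in the dosing interval), and weeks 24/48 (trough
plus a post-dose sample uniform on 0.5-2 h). Day-1 predose samples are
recorded with concentration zero (no prior doravirine) and flagged
`MDV = 1`; all later samples are treated as steady state, which the
default parameters reach well before week 4 (elimination half-life
about 18 h).

The default generative truth — $TVCL = 5.66$ L/h, $TVV = 150$ L,
$TVKA = 1$ h$^{-1}$, $\omega_{CL} = 0.23$, $\omega_V = 0.15$,
$\omega_{ka} = 0.45$, $\sigma_{prop} = 0.2$ — was chosen once so that the
typical steady-state exposures (AUC$_{0-24}$ 41.5 µM·h, $C_{max}$ about
2360 nM, $C_{24}$ about 1100 nM) and their spread are of the magnitude
reported for this compound at this dose. These are plausible stand-ins,
*not* published estimates: the published typical values and covariate
coefficients are in a supplement that is not publicly archived. Efficacy is
generated from a logistic truth centred at the typical subject's exposure
with baseline responder probability 0.90 and slope 0 by default — a flat
exposure-response. About 8% of subjects have missing week-48 RNA, split
40/60 between lack-of-efficacy discontinuation and other reasons; these
rates are invented (no published rates exist) and fully configurable.

What the generator does *not* emulate: assay quantification limits and BLQ
censoring, adherence variation and dropout over time, enzyme-induction
washout after switching from an inducer, multi-compartment disposition, and
correlated random effects. Passing recovery tests therefore demonstrate the
estimator's correctness under the stated model, not robustness to those
real-data features.

## Validation problem sizes and numerical choices

The test suite validates parameter recovery at two design points: a
300-subject, 8-sample-per-subject steady-state profile study (all fixed
effects within 10% of truth, variances within 40%), run with deliberately
wide, informative covariate distributions (weight CV 50%, age SD 20 years,
$\beta_{age} = -1$) so that every coefficient carries enough information
for a 10% check to be meaningful; and the sparse switch-trial design at 150
subjects, where typical clearance is recovered within 15%. The
slope-test type-I error is checked over 500 seeded replicates of the flat
443-subject trial (rejection fraction within [0.025, 0.085]). These sizes
were chosen as the smallest designs at which the respective checks are
statistically meaningful.

Numerical details worth knowing: residual SDs are floored at $10^{-12}$ to
keep degenerate predictions finite; non-positive-definite inner Hessians
are ridged and reported; the equal-rate branch triggers at relative rate
difference $10^{-8}$; quantiles everywhere are type-7 (linear
interpolation), switchable only by editing the summary calls; and all
simulation randomness flows from a single integer seed, so every pipeline
run is exactly reproducible.

## Limitations

The estimator is a Laplace approximation: with very few observations per
subject and large variances its likelihood differs from adaptive
quadrature, which is why the quadrature agreement is asserted only at
moderate designs. Correlated random effects (full $\Omega$), SAEM-style
stochastic estimation, covariate model search, BLQ likelihood
contributions, and between-occasion variability are out of scope. The
exposure-response module fits only the linear/log single-predictor pair;
the flat relationship in the emulated setting gives no basis for richer
structural forms.
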