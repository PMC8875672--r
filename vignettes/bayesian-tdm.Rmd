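---
title: "Bayesian therapeutic drug monitoring: models, estimation, and validation design"
author: "TDMBayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian therapeutic drug monitoring: models, estimation, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TDMBayes)
```

## The problem

Therapeutic drug monitoring (TDM) adjusts a patient's dose from one or a
few measured drug concentrations. With so little data per patient, the
individual pharmacokinetic (PK) parameters cannot be estimated from the
data alone: a population prior carries most of the information, and the
patient's measurements update it. TDMBayes implements this individual
Bayesian estimation for four drugs whose kinetics span the standard model
zoo:

| drug | structural model | estimated parameters |
|---|---|---|
| amikacin | 1-compartment IV infusion | CLslope, CLnr, Vnr |
| vancomycin | 2-compartment IV infusion | CLslope, CLnr, Vnr, k12, k21 |
| theophylline | 1-compartment, first-order absorption (ka 0.27 1/h, F 1 fixed) | CLnr, Vnr |
| phenytoin | Michaelis-Menten elimination, zero-order absorption (CLslope 0.01, F 0.92 fixed) | Vmax, km, Vnr |

## Population model

Covariates enter through lean body weight (LBW, sex-specific quadratic in
weight and height) and creatinine clearance (Cockcroft-Gault evaluated on
LBW, with the 0.85 female factor). For the linear drugs

$$\mathrm{CL} = \mathrm{CL_{slope}}\cdot \mathrm{CrCl} + \mathrm{CL_{nr}}\cdot \mathrm{LBW}, \qquad V = \mathrm{V_{nr}}\cdot \mathrm{LBW},$$

with CrCl in L/h inside the equations (1 mL/min = 0.06 L/h) and CLnr
converted from its printed per-kg unit. Phenytoin clearance is
concentration-dependent, $\mathrm{CL}(C) = V_{max}/(k_m + C) +
\mathrm{CL_{slope}}\cdot\mathrm{CrCl}$, so only its volume comes from the
covariate model; we read the registry's volume rule allometrically,
$V = \mathrm{V_{nr}}\cdot 70\cdot(\mathrm{TBW}/70)^{0.6}$, which equals
$\mathrm{V_{nr}}\cdot\mathrm{TBW}$ at 70 kg. The registry's printed
phenytoin $V_{max}$ unit (per kg per day) is physiologically impossible as
printed (a 70 kg adult would eliminate tens of grams per day); we carry it
as mg/day total, consistent with the external-model values and with
typical adult phenytoin Vmax, and convert to mg/h at the model boundary.
Both readings are isolated behind single functions.

Interindividual variability is lognormal: each estimated parameter is
$P = \bar P\, e^{\eta}$, $\eta \sim N(0, \omega^2)$ with
$\omega^2 = \ln(\mathrm{CV}^2+1)$. $\bar P$ is therefore the *median*
(typical value) on the natural scale, not the arithmetic mean, and the
arithmetic mean is used nowhere. Residual error is additive-proportional:
$\sigma_i = \mathrm{CV_{assay}}\cdot C_{pred,i} + S_{assay}$ (0.15 and
0.25 mg/L for amikacin, vancomycin and theophylline; 0.10 and 1.0 mg/L for
phenytoin).

The registry's truncation bounds are applied only when *simulating*
virtual patients (rejection sampling); the estimation prior is the
untruncated lognormal. How the legacy dosing program this registry descends from treated the
bounds during estimation is not documented anywhere we could verify, and an untruncated
prior keeps the posterior smooth for gradient-based sampling.

## Forward models

The three linear models use closed forms: superposed exponentials with
infusion handled per exponential term (during an infusion of rate $R$,
each term contributes $R B_j/\lambda_j\,(1-e^{-\lambda_j t})$), the
two-compartment model through its hybrid rate constants (the roots of
$\lambda^2-(k_{10}+k_{12}+k_{21})\lambda+k_{10}k_{21}$), and oral
absorption through the Bateman equation with an explicit $k_a = k_e$
limiting form ($C \propto t e^{-k_a t}$) entered when the rates agree to
within $10^{-8}$ relative. Steady state under a $\tau$-periodic regimen is
analytic: each exponential term accumulates by
$e^{-\lambda\tau}/(1-e^{-\lambda\tau})$.

Phenytoin has no closed form; its single ODE
$\dot A = \mathrm{in}(t) - [V_{max} C/(k_m+C) + \mathrm{CL_{lin}}C]$,
$C = A/V$, is integrated by a fixed-step classical Runge-Kutta scheme
marched exactly through every input breakpoint (doses deliver
$F\cdot\mathrm{amt}$ at zero-order rate over $\mathrm{amt}/\mathrm{rate}$
hours). The profile is smooth between breakpoints, so fixed-step RK4 at
step 0.005 h (truth generation, default kernels) is far below $10^{-6}$
relative error; inside the samplers a 0.1 h step is used, which on these
horizons still carries error orders of magnitude below the residual
noise. Phenytoin "steady state" is represented by the 20th consecutive
dose: with saturable elimination near-saturation concentrations approach
steady state extremely slowly and an analytic accumulation does not
exist, so the study convention is a fixed 20-dose history (sampled within
the 20th interval, scored within the 21st).

All kernels are templated C++ evaluated either on `double` or on
`std::complex<double>`: gradients of the log-posterior are taken by
complex-step differentiation ($\mathrm{Im}\,f(\eta+ih)/h$, $h=10^{-20}$),
which is exact to machine precision with no subtractive cancellation and
covers the ODE model with the same code path.

## Estimation

**HMC.** The posterior over $\eta$ combines $N(0,\omega_k^2)$ priors with
the heteroscedastic Normal likelihood ($\sigma$ recomputed from the
current prediction). Sampling is a dynamic (No-U-Turn) Hamiltonian Monte
Carlo: leapfrog integration, slice-based tree doubling with the standard
U-turn criterion, divergence flagging at an energy error of 1000, dual
averaging of the step size towards a 0.8 acceptance target
($\gamma=0.05$, $t_0=10$, $\kappa=0.75$), and a diagonal mass matrix
estimated from the middle half of warmup (variance regularized towards
$10^{-3}$ as $n/(n+5)$, after which the step size is re-found and
re-averaged). Four chains of 2500 warmup + 2500 sampling iterations are
the default; a named "reduced" preset (500/500) serves the large
validation sweeps. Chains start at $\eta \sim N(0, 0.1^2)$, near the prior
mode, mimicking common engine defaults. The point estimate is the
posterior median of the pooled draws (means and intervals are also
reported but nothing downstream uses them). Convergence is summarized by
rank-normalized split R-hat and a bulk effective sample size (Geyer
initial-positive-sequence truncation); a fit with R-hat above 1.1 is
returned flagged, never silently accepted, and the validation harness
excludes and counts such fits.

**MAP.** The maximum a posteriori estimator minimizes
$$\Phi(\eta) = \sum_i \frac{(C_{obs,i}-C_{pred,i})^2}{\hat\sigma_i^2}
 + \sum_k \frac{\eta_k^2}{\omega_k^2},$$
with $\hat\sigma_i$ recomputed from the prediction at every evaluation,
by BFGS with complex-step gradients, multi-started from the prior mode
plus jittered starts (SD $0.5\,\omega$); the best $\Phi$ wins. Note
$\Phi$ omits the $\log\sigma$ term of the exact negative log-posterior:
it is the classical penalized least-squares objective, kept verbatim.
With no observations the minimizer is exactly the prior typical values.

## Dose targets and recommendation

Three steady-state targets are supported: concentration at time $t$ after
the dose, AUC over one dosing interval, and average concentration
AUC$/\tau$. AUC is computed by trapezoid on a 0.05 h grid rather than by
a closed form so that one code path serves the linear and the saturable
models; on the linear models the grid error is below 0.1%. The
recommended dose is the proportional rule
$D_{rec} = D_{cur}\cdot \mathrm{target}/\mathrm{status}$, identical for
all three modes. For the linear drugs this closes the loop exactly (up to
numerics); for phenytoin it deliberately does not — saturable elimination
makes concentration super-linear in dose — and the advisor attaches an
explicit nonlinearity warning rather than inventing an
iteration the proportional rule does not define.

## The virtual cohort

The simulation study draws demographics from a reference adult hospital
cohort: height $N(165.1, 8.7^2)$ cm, weight $N(65.1, 10.2^2)$ kg, age
$N(50.2, 17.1^2)$ y, truncated by resampling to [140, 200], [35, 120],
[18, 90]. Sex ratio and serum creatinine are not part of the reference
demographics; we chose Bernoulli(0.5) sex and lognormal sCr (median 1.1 mg/dL, log-SD
0.2, truncated to [0.4, 3.0]) once, calibrated so that the cohort-scale
clearance components (mean CLnr·LBW and CLslope·CrCl over 1000 patients)
land on a realistic renal-function scale (cohort-mean CrCl near 50 mL/min); both choices are isolated in the generator.
True parameters come from the bounded lognormal priors (internal arm) or
from the four external literature models (external arm) — including the
external theophylline model's fixed ka 0.0773 1/h, elderly factor 0.876
for age ≥ 65, and exponential residual error, and the external phenytoin
model's $(1+\eta)$ variability with non-positive factors redrawn.
Observed concentrations add the residual error; internally-generated
additive errors are redrawn while the observation is non-positive (assays
report positive values), which adds a small positive bias exactly where
$S_{assay}$ is large relative to the concentration, i.e. at phenytoin
single-dose troughs.

What the generator deliberately does not emulate: comorbidity or
co-medication covariates, assay censoring at a quantification limit,
model misspecification beyond the external models, and real sampling-time
jitter. Passing validation therefore demonstrates correct transplantation
of the stated population models and estimator — not performance on real
patients.

## The validation harness

The 32 scenarios are the full grid of four drugs, two dose cases (single
dose, steady state) and four sampling sets (peak, trough, peak+trough,
hourly) under the standard regimens (amikacin 500 mg at 1000 mg/h q8h;
vancomycin 1000 mg at 500 mg/h q12h; theophylline 200 mg oral q12h;
phenytoin 100 mg at 50 mg/h zero-order q8h). Each virtual patient is
fitted with the internal prior; concentrations are then predicted one
dosing interval after the sampling times (peak observed after dose 1 is
scored at the peak after dose 2; steady-state samples score in the
following interval; phenytoin steady state scores in the 21st interval)
and compared with the noise-free truth from the true parameters. Bias and
precision are
$$\mathrm{MPE} = \frac{1}{N}\sum \frac{EST-TRUE}{TRUE}\times 100\%,\qquad
\mathrm{RMSE} = \sqrt{\tfrac{1}{N}\sum (EST-TRUE)^2},$$
pooled over all patients and evaluation times; zero-truth elements are
excluded from MPE with a warning (they cannot occur under the standard
scenarios). Parameter-level metrics are scored directly in the internal
arm; in the external arm the two parameterizations are first mapped onto
shared quantities (absolute CL and V for the linear drugs — central V for
vancomycin, whose peripheral parameters have no faithful mapping and are
excluded — and Vmax/km/V for phenytoin).

Scenario data depend only on the seed and the scenario, never on the
estimator, so HMC and MAP sweeps see identical virtual patients.

**Problem sizes.** The package supports the full study scale (1000
patients per internal scenario, 300 external), but the test suite and the
acceptance script run the desk-scale design: 200 patients per internal
scenario (100 for the phenytoin single-dose cell) and 100 external, with
the reduced sampler preset. At this scale the Monte-Carlo standard error
of a scenario MPE is roughly 0.3–1 percentage point for the linear drugs
and several points for phenytoin, whose error distribution is strongly
skewed at single-dose concentrations near $S_{assay}$.

**A note on pooling.** With several evaluation times per patient the
printed MPE/RMSE formulas (indexed by patient) do not pin down whether
errors are pooled over patient-time pairs or first aggregated within a
patient. We pool over all patient-time pairs, the convention that treats
every scored concentration equally; within-patient aggregation would
partially cancel opposite-signed errors along the profile and lower
multi-sample RMSE cells by 20–40% while leaving single-sample cells
unchanged. The choice matters whenever multi-sample cells are compared
across implementations.

## Numerical choices, degenerate inputs, tie-breaks

- ODE integration: RK4 step 0.005 h for truth generation and oracle-grade
  prediction, 0.1 h inside samplers; both configurable per call.
- Oral absorption with $k_a \approx k_e$: limiting form entered below
  $10^{-8}$ relative separation.
- Negative ODE states are clipped at zero (cannot occur under positive
  parameters except by roundoff at the origin).
- Same-time dose and observation rows: the dose sorts first; infusion
  starts are continuous so the observation reads the pre-bolus
  concentration only for instantaneous doses.
- Multi-start MAP ties: the lowest $\Phi$ wins; equal values keep the
  earliest start (prior mode first).
- Rejection sampling guards: 1000 attempts per parameter against the
  registry bounds, then an explicit prior-configuration error.
- All RNG flows through explicit seeds; per-patient fit seeds are derived
  deterministically from the scenario seed, and the sampler's own RNG is
  a seeded Mersenne Twister with Box-Muller normals, so identical calls
  are bit-reproducible.

## Known limitations

- No lag times, transit absorption, or protein-binding corrections; no
  drugs beyond the four; no hierarchical population fitting.
- The proportional dose rule is approximate for phenytoin by design.
- The sex and serum-creatinine distributions of the virtual cohort are
  this package's calibrated choices; cells dominated by prior-driven
  shrinkage (sparse sampling sets) are sensitive to them.
- Validation is entirely simulation-based; nothing here demonstrates
  performance on real TDM data.
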