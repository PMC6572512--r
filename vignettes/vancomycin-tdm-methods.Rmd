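---
title: "Methods: the vancomycin population PK model behind vancotdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the vancomycin population PK model behind vancotdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancotdm)
```

## The model

vancotdm implements model-informed precision dosing for intravenous
vancomycin on top of a two-compartment disposition model with zero-order
(infusion) input and first-order elimination. Amounts in the central
(volume $V_1$) and peripheral ($V_2$) compartments follow

$$\frac{dA_1}{dt} = in(t) - (k_{10}+k_{12})A_1 + k_{21}A_2, \qquad
  \frac{dA_2}{dt} = k_{12}A_1 - k_{21}A_2,$$

with $k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$ and
$in(t) = \text{dose}/\text{duration}$ while an infusion runs. The observed
quantity is the central concentration $C = A_1/V_1$ in mg/L; time is in
hours, doses in mg, volumes in L, clearances in L/h throughout, so no unit
conversion factors appear anywhere.

Renal function drives clearance through three mutually exclusive regimes:

$$CL = \begin{cases}
  \theta_1\,(CLCR/72)^{\theta_2} & \text{no renal replacement}\\
  CL_{CRRT} & \text{continuous renal replacement therapy}\\
  CL_{HD} & \text{hemodialysis,}
\end{cases}$$

with $CLCR$ the Cockcroft–Gault creatinine clearance (mL/min), and body
weight scales the peripheral volume, $V_2 = \theta_3\,(WT/60)$. The
packaged default parameters (`default_params()`) are the final estimates
from a population analysis of routine Korean TDM data (220 patients, 1020
concentrations): $\theta_1 = 2.82$ L/h, $\theta_2 = 0.836$,
$CL_{CRRT} = 0.716$ L/h, $CL_{HD} = 0.334$ L/h, $V_1 = 31.8$ L,
$Q = 11.7$ L/h, $\theta_3 = 75.4$ L. The reference points (CLCR 72 mL/min,
weight 60 kg) are fields of the parameter object, not buried literals.

Between-subject variability (BSV) is log-normal on $CL$ and $V_2$ only —
the two parameters with estimated variance components —
$P_i = P_{typ}e^{\eta_i}$, $\eta \sim N(0,\omega^2)$, entered on the
conventional CV% scale ($\omega_{CL}$ 99.2%, $\omega_{V_2}$ 49.2%) and
converted with the standard log-normal relation
$\omega^2 = \ln(1 + (CV/100)^2)$. We deliberately use the form with the
square root, $CV = \sqrt{e^{\omega^2}-1}$, the convention under which
NONMEM-style CV% reporting of those magnitudes is coherent. Residual error
is combined: $Var = \sigma_{add}^2 + (\sigma_{prop}F)^2$ around a
prediction $F$; the default is purely proportional with
$\sigma_{prop} = 0.253$ treated as a standard deviation (≈25% CV), the
conventional reading of a unitless proportional error estimate of that
size. `V1` and `Q` carry no random effects; a documented alternative would
have been an $\eta$ on $V_1$, but a random effect without an estimated
variance cannot enter the MAP prior penalty, so the $\omega$-bearing pair
$(CL, V_2)$ is the only defensible choice.

## Concentration prediction

The production path is the closed-form solution: each infusion contributes

$$C_d(t) = \frac{R}{V_1}\left[A\,g(\alpha,\tau_e)e^{-\alpha\tau_p} +
  B\,g(\beta,\tau_e)e^{-\beta\tau_p}\right],$$

where $R$ is the infusion rate, $\tau_e$ the elapsed infusion time,
$\tau_p$ the time since the infusion ended, $g(\lambda,\tau) =
(1-e^{-\lambda\tau})/\lambda$, $A = (\alpha-k_{21})/(\alpha-\beta)$,
$B = (k_{21}-\beta)/(\alpha-\beta)$, and $\alpha,\beta$ the hybrid rate
constants. Doses superpose linearly — the model is linear and
time-invariant — so multi-dose curves are exact with no discretization
error, and the AUC over any window is the analytic integral of the same
expression (`auc_window()`), not a trapezoidal sum.

Numerical care: the discriminant of the $\alpha/\beta$ quadratic is
evaluated as $(k_{10}+k_{12}-k_{21})^2 + 4k_{12}k_{21}$, which is free of
cancellation, and $\beta = k_{10}k_{21}/\alpha$ uses the product identity.
When $Q = 0$ the peripheral compartment decouples; $\beta = 0$ and
$g(0,\tau) = \tau$ are handled as exact limits, so the engine degrades
gracefully to the one-compartment infusion model (verified against the
independent closed form in the tests).

`ode_conc()` is a deliberately independent oracle — piecewise `lsoda`
integration across infusion breakpoints at $10^{-11}$ tolerance — used by
the test suite to validate the closed form to better than $10^{-6}$
relative; it is never the production path.

Steady-state anchors follow clinical TDM convention, which the source
analysis did not pin down: the peak is sampled at the end of the last
infusion and the trough at the end of the last dosing interval
(immediately pre-dose), with the interval inferred from the last two dose
times. Dosing intervals are half-open $[start, start+\tau)$; an
observation at exactly a dose time is attributed pre-dose.

## MAP empirical-Bayes estimation

Individualization minimizes the $-2$ log posterior (up to the constant
$\ln 2\pi$ terms, which do not move the argmin):

$$O(\eta) = \sum_j\left[\ln\sigma_j^2 +
  \frac{(y_j - F_j)^2}{\sigma_j^2}\right] + \eta^T\Omega^{-1}\eta,$$

with natural logs, $\sigma_j^2$ the combined residual variance at $F_j$,
and $\Omega = \mathrm{diag}(\omega^2_{CL}, \omega^2_{V_2})$. $\Omega$ is
diagonal because no covariance component is estimated in the default
model; `map_objective()` accepts a full matrix for forward compatibility.
Optimization is over the 2-vector $(\eta_{CL}, \eta_{V_2})$ with a
multi-start scheme — $\eta = 0$ plus $\pm 1$ SD perturbations along each
axis — each start running Nelder–Mead and a BFGS polish at relative
tolerance $10^{-10}$ on the objective, best value wins. With no usable
observations the prior mode $\eta = (0,0)$ is returned exactly.
Observations above the outlier ceiling (default 100 mg/L, configurable)
are excluded from fitting and counted, never silently dropped from the
dataset.

Two properties of this estimator are worth knowing. First, shrinkage: with
sparse data the prior pulls $\eta$ toward 0, so a single level never fully
determines $CL$. Second, with a purely proportional error model the
$\ln\sigma_j^2$ term mildly rewards smaller predictions; parameter-recovery
experiments should therefore match the fitting residual model to the
generating one (the test suite's recovery study simulates 5% proportional
noise and fits with $\sigma_{prop} = 0.05$, recovering known etas with
median absolute error well under 0.15).

## Population simulation

`simulate_population()` draws $\eta$ pairs, forms individual parameters,
evaluates the closed-form curves on a 0.25-h grid and summarizes the
pointwise median and 90% prediction interval, plus per-subject peak,
trough and AUC$_{24}$. Default profiles are error-free true
concentrations: residual error is measurement noise, not exposure, and is
therefore opt-in (it is used when emulating observed samples, as in the
VPC). The four standard scenario groups (`scenario_groups()`) fix the
conditions of the reference simulation experiment — CLCR 100 and
40 mL/min, CRRT, and HD, all at 60 kg on 1 g daily for 7 days as 1-h
infusions, 1000 subjects.

A note on reading those simulations: the population median equals the
typical-subject curve (the log-normal median is the typical value), and
because day 7 is ~7 elimination half-lives for a normal-renal-function
subject, the day-7 trough is within a few percent of true steady state.
The skew of the log-normal population makes arithmetic means visibly
higher than medians (e.g. mean trough ≈ 9.6 vs median ≈ 6.6 mg/L in the
normal-renal-function group); we report medians, and the acceptance
machinery computes exactly those.

## Prediction-corrected VPC

`vanco_vpc()` implements the prediction-corrected visual predictive check:
observations are binned by time since first dose (half-open bins; the
default edges 0, 8.5, 12.5, 24.5, 48.5, 76, 100, 200, …, 900 h follow the
sampling density of routine TDM and are fully overridable), corrected by
$y \cdot \widetilde{PRED}_{bin}/PRED_{ij}$ with $PRED$ the $\eta = 0$
typical prediction under each subject's own covariates, and compared with
confidence intervals of the same percentiles across simulated replicates.
Replicates reuse each subject's exact design — dosing history, covariates
and sampling times — which is standard VPC practice; each redraws the
etas and adds combined residual error. Only the prediction correction is
applied; the additional variability correction of the full "pvc" scheme
is intentionally out of scope, and empty bins are reported with zero
counts rather than dropped.

## Dose advice

`evaluate_regimen()` and `search_regimens()` mirror the interactive
dose-adjustment workflow: steady-state metrics of a candidate regimen are
scored against a target specification (default trough window 10–20 mg/L
and AUC$_{24} \ge 400$ mg·h/L, both user-adjustable per indication), and
a grid of doses × intervals × infusion durations is ranked by distance of
the trough from the window midpoint, with deterministic tie-breaks (lower
dose, then longer interval). Evaluation uses a 7-day horizon rather than
$t \to \infty$ — the same horizon as the simulation experiment, and a
clinically honest notion of "steady state approached" for a drug with a
~23-h terminal half-life at normal renal function; the horizon is a
parameter.

## Synthetic data

`simulate_tdm_dataset()` generates NONMEM-style test cohorts: covariates
uniform over ranges spanning a routine hospital TDM population (age 21–98
years, weight 30–126.7 kg, CLCR 4.57–279 mL/min), etas from the BSV
distribution, and observations at realistic TDM sampling anchors
(post-infusion peaks, pre-dose troughs) with combined residual noise,
alongside a truth table of the generating etas for recovery studies. What
it does not emulate: covariate correlations (age–creatinine, weight–sex),
intra-course renal-function changes (HD/CRRT are whole-course flags, as
in the model), irregular dose amounts or missed doses, and assay
censoring below a quantification limit. Passing tests on these cohorts
therefore demonstrate internal consistency of the estimation and
diagnostic machinery under the model's own assumptions, not robustness to
the messiness of real TDM records.

## Problem sizes and numerical choices

The test suite and acceptance script use 1000 virtual subjects for
scenario simulations (matching the reference experiment), a 24-subject ×
200-replicate VPC self-consistency study with one observation per default
bin, and a 20-seed MAP recovery study — sizes chosen so the full suite
runs in minutes on a laptop while keeping Monte-Carlo error well inside
the asserted tolerances. Convergence tolerance for MAP is $10^{-10}$
relative on the objective; closed-form vs ODE agreement is asserted at
$10^{-6}$ relative at ODE tolerance $10^{-11}$; CV↔$\omega^2$ roundtrips
are exact to $10^{-12}$.

## Known limitations

- Population parameters are fixed inputs: no population re-estimation,
  covariate screening, or bootstrap machinery.
- HD/CRRT enter only through clearance; intra-dialysis kinetics and
  session timing are not modeled.
- MAP point estimates only — no posterior sampling, so reported individual
  parameters carry no uncertainty intervals.
- The default renal-function input is Cockcroft–Gault; MDRD/CKD-EPI are
  intentionally not offered with this parameterization, whose reference
  point (CLCR 72 mL/min) is Cockcroft–Gault-based.
- Credibility degrades for very long courses (weeks), where the
  underlying data were sparse.
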