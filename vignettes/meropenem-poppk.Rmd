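---
title: "Methods: meropenem population PK and target-attainment simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meropenem population PK and target-attainment simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the structural and statistical model, the estimation machinery, the
simulation layer, the synthetic study generator, and the numerical and
design choices made where the design was genuinely open.

## Structural model

Meropenem disposition is described by a mammillary two-compartment model
with first-order transfer and elimination and zero-order (constant-rate)
infusion input. We parameterise by clearance `CL`, central volume `Vc`,
inter-compartmental clearance `Q` and peripheral volume `Vp`; the
steady-state distribution volume is `Vss = Vc + Vp`. With micro-constants
`k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`, the hybrid rates `alpha, beta`
solve `alpha + beta = k10 + k12 + k21`, `alpha * beta = k10 * k21`, and the
central concentration after one infusion, and at steady state under
repeated dosing, follow the standard bi-exponential closed forms; multiple
dosing closes the geometric series on each exponential term rather than
summing doses numerically. A note on wording: all drug *input* is
constant-rate over the infusion duration — "first-order kinetics"
describes the disposition processes, not the infusion.

One numerical subtlety: when `alpha == beta` (a repeated root, reachable
only on a measure-zero parameter set) the generic expressions divide by
`alpha - beta`. The implementation floors the discriminant at a relative
1e-9, equivalent to evaluating the limit with a perturbation three orders
of magnitude below the package-wide 1e-6 accuracy contract. Tests include
a near-degenerate parameter set against the ODE oracle.

The production path for profiles is the closed form, evaluated on a 0.02 h
grid over one dosing interval with the end-of-infusion breakpoint inserted
exactly. The closed form is verified against a stiff ODE integration
(deSolve, rtol 1e-11) at relative tolerance 1e-6 over randomised parameter
sweeps, and steady-state mass balance (`AUC * CL = dose`) is checked by
adaptive quadrature rather than trapezoids so the test measures the
solution, not the grid.

## Covariate, variability and error models

Typical clearance is linear in the CKD-EPI eGFR (`CE`, mL/min/1.73 m²)
centred at 91.57:

```
TVCL = theta_cl * (1 + theta_cov * (CE - 91.57))
```

The linear form can cross zero for extreme slope/eGFR combinations (it
happens in bootstrap replicates); the value is floored at 0.01 L/h with a
warning rather than reparameterised, so the packaged estimates stay
interpretable exactly as published.

Inter-individual variability is log-normal on `CL`, `Vc` and `Vp`
(`P_i = TVP * exp(eta)`, `eta ~ N(0, omega^2)`, no eta-eta correlations);
`Q` carries none — the fitted model reports IIV only for clearance and the
two volumes, and we read its "V1, V2" as `Vc`, `Vp`. Residual error is
power-scaled proportional, `Y = F + F^power * eps`, `eps ~ N(0, sigma^2)`.
The source analysis reports a "proportional error" of 24.6% together with
a power parameter of 0.865 without printing the expression; the
conventional NONMEM-style reading above is used, and `power = 1` recovers
a pure proportional model, so the exponent is exposed rather than baked
in. The unbound fraction is fixed at 0.98 and applied only in the
pharmacodynamic layer (binding kinetics are out of scope).

## Renal-function equations

Cockcroft-Gault creatinine clearance, 4-variable MDRD and 2009 CKD-EPI
creatinine eGFR, Du Bois BSA, and BSA de-indexing
(`GFR[mL/min] = GFR[indexed] * BSA / 1.73`) are implemented as pure
functions. Two deliberate choices:

* **Race coefficients are omitted** from MDRD and CKD-EPI. The model was
  developed in an all-Korean cohort and never applies them; carrying them
  would suggest a knob the analysis does not have.
* MDRD uses the IDMS-traceable **175** coefficient by default; the
  non-IDMS 186 variant is available via an argument since the source does
  not state which assay calibration applied.

Cystatin C travels as a covariate column (it was screened as a raw
covariate) but no cystatin-based eGFR equation is implemented.

The simulation axis conflation deserves a note: the dose-banding rule is
stated in creatinine-clearance units while the covariate model consumes
CKD-EPI eGFR, and the source uses the symbols interchangeably when
labelling simulation bands. The package treats the simulation axis as
CKD-EPI eGFR throughout — it is the quantity the covariate model is
estimated against — and feeds the same value to the banding rule.

## Estimation

The marginal likelihood of each subject is approximated by the Laplace
method: the inner problem maximises the conditional joint density of the
subject's observations and random effects (residual variance evaluated at
the conditional prediction — the "interaction" convention), and the
subject's contribution adds the log-determinant of the curvature at the
mode. Additive `2*pi` constants are dropped, so differences between nested
models follow the usual chi-square thresholds (3.84/5.99 at p<0.05, 6.635
forward, 10.83 backward). This is an in-spirit FOCE/Laplace estimator;
matching any specific software's printed objective values is explicitly
not a goal, and the published fit's OFVs are not reproduction targets
(they require the original patient data).

Implementation: the inner 1-3 dimensional optimisation is a damped Newton
search (finite-difference gradient and Hessian, Levenberg ridge on
failure) written in C++, restarted from `eta = 0` at every outer iteration
for determinism; the outer optimiser is `nlminb` over the structural
parameters on the identity scale (box-constrained positive) and the
variance-scale parameters (`omega`, `sigma`, `power`) on the log scale,
with relative OFV tolerance 1e-6. Standard errors come from the numerical
Hessian of the outer objective, delta-method transformed back to the
natural scale; IIV is reported as the SD of `eta` (for log-normal IIV,
`100 * omega` approximates the %CV — an approximation we document rather
than hide). The Laplace objective is validated against a 64-node
Gauss-Hermite quadrature of the exact marginal likelihood on
single-subject problems, and against the naive-pooled likelihood in the
`omega -> 0` limit.

Observations below the 0.2 mg/L quantitation limit are **dropped from the
likelihood** and counted. This is the simplest defensible rule (the source
is silent on BLQ handling); likelihood-based censoring (M3) is a known
alternative and a deliberate non-feature here. The pre-dose sample before
the first dose is retained in datasets as a flagged zero rather than
deleted, so row counts match the design.

## Diagnostics

* **CWRES**: observations minus the FOCE-linearised population prediction
  `f(eta_hat) - G * eta_hat`, decorrelated by the Cholesky factor of
  `G Omega G' + V(eta_hat)`. Under a correct model these are approximately
  standard normal. At the packaged IIV magnitudes (omega up to 0.44) the
  linearisation of the exponential parameter link leaves a small negative
  mean (about -0.03, measured over ten thousand self-simulated residuals)
  — a property of first-order conditional residuals, not a defect; the
  calibration tests therefore use replicates large enough that Monte Carlo
  error is small against the +/-0.1 tolerance.
* **Shrinkage**: `100 * (1 - sd(eta_hat)/omega)` per random effect;
  undefined when `omega` is fixed at zero.
* **pcVPC**: simulated replicates of the observed design are compared with
  observations after both are scaled by the bin-median population
  prediction. With a proportional-type residual model this prediction
  correction also corrects the variability, which is why no separate
  variability scaling is applied; with correction disabled and a
  homogeneous design the procedure reduces to a classical VPC (tested).
  Default bins are one per distinct nominal sampling time; empty bins
  merge leftwards.
* **Bootstrap**: nonparametric over subjects, percentile intervals,
  non-converged replicates counted and excluded, warning above 20%
  failures.

## The four simulations

1. **Empirical therapy**: virtual patients receive an eGFR from a
   log-normal law truncated to (0, 130] mL/min, the renally banded
   recommended regimen (>50: 1 g q8h; 26-50: 1 g q12h; 10-25: 0.5 g q12h;
   <10: 0.5 g q24h; 30-min infusions), and a random MIC from a
   user-supplied frequency table. The source states the eGFR law's range
   but not its parameters; we use median 90 mL/min/1.73 m² (the study
   cohort's median eGFR was ~91.6) and log-scale SD 0.5, both exposed in
   the sampler argument. PTA is computed *conditionally* on each MIC value
   over the whole cohort rather than by binned random assignment — the
   estimators have the same expectation, the conditional one has lower
   variance. The MIC-weighted overall attainment follows by the law of
   total probability. The infusion duration of the recommended regimen is
   0.5 h (the study administered 30-min infusions; the simulation section
   does not restate it).
2. **-4. Dose-finding grids** for the targets 40%fT>MIC, 100%fT>MIC and
   100%fT>4xMIC: eGFR uniform within each of six bands ((0,10] ...
   (130,170] mL/min), all combinations of dose (0.5/1/2 g), interval
   (8/12 h), infusion duration (0.5/1/2/3 h) and MIC (0.060-16 mg/L).
   The source's "1000 individual PK parameters" is read as 1000 virtual
   patients *per band* (stable PTA estimates); the size is a parameter.
   Within a band the same virtual cohort is shared across regimens and
   MICs — a variance-reduction device that makes within-band comparisons
   paired (and cells of one band correlated).

`fT>MIC` is evaluated over one steady-state interval on the 0.02 h grid
with threshold crossings located by linear interpolation between grid
points; by periodicity this equals the 24-h fraction for any interval
dividing 24 h. Attainment uses `f * C(t) > multiplier * MIC` with
`f = 0.98`. A regimen is adequate at PTA >= 90%; with 10,000 virtual
patients the Monte Carlo standard error near 90% is about 0.3 percentage
points, and acceptance checks allow +/-2.

The packaged MIC table (`inst/extdata/mic_distribution_synthetic.csv`) is
a synthetic doubling-dilution illustration so the pipeline runs
self-contained; it is *not* a surveillance distribution, and any inference
about a real pathogen requires the user's own frequency table.

## Synthetic study generator

The generator emulates the study design the model was developed on:
26 ICU subjects (8 on ECMO, VA:VV odds 7:1), 0.5/1 g every 8/12 h as
30-min infusions with the regimen set by the renal banding rule (the
q24h band is clamped to 0.5 g q12h because the observed study used only
q8/q12 dosing), five samples after the first dose (pre-dose, 0.5, 1, 4,
8 h for q8h; 0, 0.5, 1, 6, 12 h for q12h), and a trough/peak pair at the
fourth or fifth dose (chosen at random per subject) forming the validation
split. Covariates come from truncated log-normal/normal marginals
moment-matched to the published cohort medians and IQRs; eGFR is always
computed from sampled creatinine, age and sex, never drawn independently.
Concentrations get the power-proportional residual noise; values below
0.2 mg/L are flagged, not removed. A timing-corruption helper shifts the
*recorded* time of chosen validation records while the value stays
simulated at the true time — the mis-documented-sampling scenario that
inflated the published external-validation errors can thus be
demonstrated, though no equivalence to the real records is claimed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: assay chemistry and drift, CRRT as a clearance
pathway, ECMO circuit adsorption (the source found no ECMO effect on PK),
correlation between covariates beyond what the renal equations induce,
time-varying renal function, and the exact 125/44
development/validation sample split (nominal sampling gives 182 samples
across 26 subjects; the split cannot be uniquely reconstructed, so the
generator reports its own counts, which land nearby once BLQ flagging is
applied).

## Problem sizes and reproducibility

Every stochastic routine consumes R's global random stream, so a single
`set.seed()` makes cohorts, studies, grids and bootstrap intervals
byte-reproducible; `run_paper_simulations()` additionally writes a
manifest (seed, config, versions). The test suite runs the full
26-subject design for parameter recovery (10 seeded replicates), 10,000
virtual patients per acceptance PTA cell, 300-subject replicates for
residual calibration, and reduced sizes (hundreds of patients, tens of
bootstrap replicates) for the remaining property checks — sizes chosen so
each check's Monte Carlo error is small against its tolerance.

## Known limitations

* The estimator is Laplace-based; it will not reproduce any specific
  software's printed objective values or the published fit's standard
  errors and bootstrap intervals, which depend on the original data.
* The linear covariate form is unbounded above and floored below; outside
  the observed eGFR range (roughly 0-170 mL/min) it extrapolates.
* BLQ handling is exclusion, not censored-likelihood.
* One covariate only; no inter-occasion variability; no full omega
  covariance.
* PTA conclusions inherit the packaged model's estimates; with a
  different population (e.g. different weight distribution) the absolute
  PTA values shift even though the machinery is unchanged.
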