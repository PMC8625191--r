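# meropk

Population pharmacokinetics and Monte Carlo target-attainment simulation
for meropenem in critically ill adults.

Beta-lactam dosing in the ICU is hard: sepsis shifts distribution volumes,
renal function ranges from anuria to augmented clearance, and efficacy is
driven by the *time* the free drug concentration stays above the pathogen's
MIC, not by peaks or averages. This package implements the full analysis
chain a population-PK study of meropenem rests on, for pharmacometricians
and infectious-disease modellers: the structural model, the mixed-effects
estimation layer, external-validation metrics, and the dose-finding
simulations — plus a synthetic study generator so every piece is testable
without patient data.

## The model

Two-compartment kinetics with constant-rate (zero-order) IV infusion input
and first-order disposition. The typical clearance carries a linear
renal-function covariate,

    CL = θ₁ · (1 + θ₂ · (CE − 91.57))        [L/h]

where CE is the CKD-EPI eGFR (mL/min/1.73 m²) centred at its reference
value 91.57. Packaged estimates: θ₁ = 6.37 L/h, θ₂ = 0.00925,
V_C = 9.07 L, Q = 10.7 L/h, V_P = 7.91 L (so V_SS = V_C + V_P = 17.0 L).
Inter-individual variability is log-normal, θᵢ = θ·exp(ηᵢ) with
η ~ N(0, ω²) on CL, V_C and V_P (ω = 0.314, 0.436, 0.366); residual error
is power-scaled proportional, Y = F + F^0.865·ε with ε ~ N(0, 0.246²).
The unbound fraction is fixed at f = 0.98.

Estimation is a Laplace approximation of the marginal likelihood at the
conditional mode of η, with the residual variance evaluated at the
conditional prediction (FOCE-with-interaction in spirit), a per-subject
Newton inner loop in C++ and a quasi-Newton outer loop. Diagnostics cover
conditional weighted residuals, η-shrinkage, nonparametric bootstrap,
covariate scanning at the ΔOFV 6.635/10.83 stepwise thresholds, and
prediction-corrected visual predictive checks.

The pharmacodynamic layer computes fT>MIC — the percentage of a
steady-state dosing interval with f·C(t) above the MIC (or 4×MIC) — and
the probability of target attainment (PTA) across doses (0.5/1/2 g),
intervals (q8h/q12h), infusion durations (0.5–3 h), MICs (0.06–16 mg/L)
and six renal-function bands (0–170 mL/min), with 90% PTA as the adequacy
bar.

## Worked example

Fit the model to a synthetic 26-subject study generated at the packaged
parameters, then ask whether 1 g q12h over 30 min is adequate for MIC
4 mg/L in moderate renal impairment:

```r
library(meropk)
m <- meropenem_model()

set.seed(42)
cohort <- generate_cohort(study_design())
ds <- generate_study(m, cohort)

init <- m; init$theta_cl <- 5; init$vc <- 7; init$theta_cov <- 0.005
fit <- fit_nlme(ds, init)
print(fit)
#> NLME fit (Laplace)
#>   OFV 624.882 | 26 subjects, 156 observations (26 BLQ dropped)
#>   convergence code 0 (relative convergence (4))
#>            estimate rse_pct fixed
#> theta_cl    6.71200    4.88
#> theta_cov   0.00916   16.00
#> vc          8.77500   11.30
#> q          11.07000   11.80
#> vp          9.10200    8.27
#> omega_cl    0.23340   15.00
#> omega_vc    0.53350   16.00
#> omega_vp    0.29490   26.30
#> sigma_prop  0.18230   19.00
#> power       0.93420    6.53
#>   shrinkage (%): eta_cl 2.3, eta_vc 3.0, eta_vp 23.4

set.seed(1)
pta(m, function(n) runif(n, 26, 50), dosing_regimen(1000, 12, 0.5),
    mic = 4, target = "FT40", n = 10000)
#> [1] 99.93
#> attr(,"adequate")
#> [1] TRUE
```

The fit recovers the generating clearance and its eGFR slope from 26 sparse
subjects (θ₁ 6.71 vs 6.37 true; θ₂ 0.00916 vs 0.00925); 26 of 182 samples
fell below the 0.2 mg/L quantitation limit and were dropped from the
likelihood. The PTA call says 99.9% of 10,000 virtual patients with eGFR
26–50 mL/min/1.73 m² keep free meropenem above 4 mg/L for at least 40% of
the interval under 1 g q12h — comfortably past the 90% adequacy bar.

`run_paper_simulations(default_run_config())` executes the full study:
the empirical-therapy cohort simulation (renally banded recommended
dosing against an MIC distribution) and the three dose-finding grids, and
writes long-format CSVs plus a seed/config manifest. The packaged MIC
table is a synthetic illustration — supply a real surveillance
distribution for inference.

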