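# gcdcaspk

Population pharmacokinetics of glycochenodeoxycholic acid 3-*O*-sulfate
(GCDCA-S), an endogenous bile-acid sulfate used as a biomarker of the
hepatic uptake transporter **OATP1B3** and the renal secretory transporter
**OAT3**. The package is for pharmacometricians and clinical
pharmacologists who want to simulate, refit, and design transporter
drug–drug-interaction (DDI) studies that monitor this biomarker instead of
dosing an exogenous probe drug.

## The model

GCDCA-S plasma concentration $C$ (µM) follows a turnover model with
zero-order synthesis and parallel first-order hepatobiliary and renal
clearances, both modulated by competitive inhibition through the unbound
concentration of a co-administered inhibitor:

$$\frac{dC}{dt} = \frac{1}{V_c}\left(k_{syn}
  - C\,\frac{CL_h}{X_{\mathrm{eff}}\left(1 + C_{u,\mathrm{RIF}}/K_{i,u,\mathrm{OATP1B3}}\right)}
  - C\,\frac{CL_R}{1 + C_{u,\mathrm{PROB}}/K_{i,u,\mathrm{OAT3}}}\right),
\qquad
\frac{dA}{dt} = C\,\frac{CL_R}{1 + C_{u,\mathrm{PROB}}/K_{i,u,\mathrm{OAT3}}},$$

where $A$ is the cumulative amount in urine (µmol), rifampicin (single
oral dose, zero-order absorption with lag) inhibits hepatic uptake,
probenecid (multi-dose, first-order absorption) inhibits renal secretion
and reduces $CL_h$ by a fixed factor $X$ while on treatment. Typical
values: $k_{syn} = 1.0$ µmol/h, $V_c = 4.8$ L, $CL_h = 15$ L/h,
$CL_R = 0.31$ L/h, $K_{i,u,\mathrm{OATP1B3}} = 0.009$ µM,
$K_{i,u,\mathrm{OAT3}} = 2.7$ µM, $X = 1.7$; log-normal inter-individual
variability and proportional residual error at the reported magnitudes.
The baseline is the steady state $k_{syn}/(CL_h + CL_R) \approx 0.065$ µM
and the urinary excretion fraction is ~2% — biliary elimination dominates.

On top of the structural core the package provides the population layer,
the three published cross-over study designs plus verification designs,
a NONMEM-style CSV dataset dialect, synthetic-data generation with truth
sidecars, sequential Laplace mixed-effects estimation, VPC bands, and the
simulation-based power calculation for OATP1B3/OAT3 DDI study design.
See `vignette("gcdcas-methods", package = "gcdcaspk")` for the methods.

## Worked example

```r
library(gcdcaspk)
pop <- default_population()

# baseline steady state (uM)
baseline_concentration(biomarker_params())
#> [1] 0.06531679

# a typical individual's interaction day: single 600 mg rifampicin dose
s <- solve_biomarker(24, list(rifampicin = dose_events("rifampicin", 0, 600)))
max(s$conc)                                   # peak biomarker concentration, uM
#> [1] 1.403517

# population-median AUC ratio (0-24 h) under 600 mg rifampicin
v <- verification_aucr(600, n_sim = 1000, pop = pop, seed = 1)
v$median_aucr
#> [1] 13.60574

# minimal sample size to detect a rifampicin-like OATP1B3 inhibitor
pg <- power_curve(power_scenario("OATP1B3", Y = 1, alpha = 0.01,
                                 replicates = 500), pop, seed = 1)
pg$minimal_n
#>    target Y alpha n_min
#> 1 OATP1B3 1  0.01     5
```

The biomarker rises ~21-fold above baseline at the peak and its 0–24 h
exposure ratio is ~13.6 — a strong, easily detected interaction: 5
subjects suffice at significance level 0.01. Synthetic three-study
ensembles (`generate_study()`, `generate_ensemble()`) refit with
`fit_population()` recover these parameters; `sim_reestimation()` wraps
the whole loop.

A thin command-line interface over the same functions is installed at
`system.file("cli/gcdcaspk-cli.R", package = "gcdcaspk")` with
subcommands `generate`, `simulate`, `fit`, `vpc`, `power`, `sensitivity`.

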