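# combopd

Pharmacodynamic analysis of cisplatin (CIS) + cimetidine (CIM) combinations
in cancer cell lines. Cimetidine blocks the OCT2 transporter and is studied
as protection against cisplatin nephrotoxicity; the question here is what it
does to cisplatin's *anticancer* effect. The package quantifies that
interaction from CCK-8-style viability data in an OCT2-negative line (Huh7)
and an OCT2-positive line (MDA-MB-468), via three linked models:

* **Inhibitory Hill concentration-response** (72 h, single agents):
  `R = R0 (1 − Imax C^γ / (IC50^γ + C^γ))`.
* **Competitive interaction model** (72 h, 6 × 6 combination grid): with
  `x = (C_A / (ψ·IC50_A))^{γ_A}` and `y = (C_B / (ψ·IC50_B))^{γ_B}`,
  `R = R0 [1 − (Imax_A·x + Imax_B·y) / (x + y + 1)]`.
  A single interaction parameter ψ scales the potency terms: ψ < 1 synergy,
  ψ = 1 additivity, ψ > 1 antagonism. The additive (ψ = 1) 3-D response
  surface is the null reference for classifying observed combination wells.
* **Cell-level PD model** (0–96 h time courses): untreated cells grow as
  `dR/dt = k_g R`; each drug drives a capacity-limited kill signal
  `K = Smax C / (SC50 + C)` through three transit compartments (mean transit
  time τ, modelling delayed death signalling), and
  `dR/dt = k_g R − (K3_CIS + K3_CIM) R`. In combination, ψ scales the
  cisplatin SC50; ψ = 1 recovers the single-agent system exactly.

Estimation is multi-start bounded Levenberg–Marquardt least squares with the
sequential workflow used in this field: fit single agents, fix them,
estimate ψ alone from the combination arms; estimates come with %RSE.
Because the original raw data are not deposited, the package includes a
synthetic-data module reproducing the study design (concentration grids,
time points, triplicates, configurable noise), so every analysis is
end-to-end reproducible and the estimators are validated by parameter
recovery.

## Worked example

Simulate a noisy Huh7 static study from the published estimates, refit it,
and interpret the interaction:

```r
library(combopd)

design <- default_design("Huh7")
truth  <- interaction_params(reference_hill("Huh7", "CIS"),
                             reference_hill("Huh7", "CIM"),
                             psi = reference_psi("Huh7", "static"))  # 0.95
plate  <- generate_static(design, truth, noise_model(0.10, 2, seed = 7))

cis_fit <- fit_hill(as_single_agent(plate, "CIS", time_h = 72))
print(cis_fit)
#> <fit_result: hill >
#>   converged: TRUE   RSS: 1567.13   n = 21
#>      estimate  rse_pct
#> imax 1.000000       NA
#> ic50 2.678579 14.37013
#>   at boundary: imax
#>   fixed: r0=100, gamma=1

cim_fit <- fit_hill(as_single_agent(plate, "CIM", time_h = 72),
                    fit_spec(free = c("r0", "imax", "ic50", "gamma")))
hill_cis <- hill_params(100, cis_fit$estimates["imax"],
                        cis_fit$estimates["ic50"], 1)
hill_cim <- do.call(hill_params, as.list(cim_fit$estimates))

psi_fit <- fit_interaction_static(as_combination(plate, 72),
                                  hill_cis, hill_cim)
#> psi = 0.907 (%RSE 2.5) -> additive

calls <- classify_points(hill_cis, hill_cim, as_combination(plate, 72),
                         tolerance = 2)
#> 18 of 108 combination wells above the additive surface
```

With 10% proportional noise on 21 wells, the cisplatin IC50 (truth 1.96 µM)
is recovered as 2.68 µM with imax pinned at its upper bound (so its Wald SE
is undefined — reported NA); ψ comes back at 0.907 against a generating 0.95
and is labelled additive at the default ±0.1 band, and only 17% of
combination wells sit above the additive surface — the synergistic/additive
signature expected for the OCT2-negative line. Noise-free recovery is exact
to optimizer tolerance (see the tests).

The staged version of the full analysis lives in `analysis/01_simulate.R`
through `analysis/05_report.R` (simulate → Hill fits → static ψ + surface →
time-course PD → combined report), each a thin driver over the package that
writes its tables under `results/`. `run_pipeline(pipeline_config(...))`
runs the same sequence in one call.

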