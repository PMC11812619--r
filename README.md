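# biovalor

Mass, energy and kinetic analysis for organic waste valorization lines.

`biovalor` is for environmental bioprocess engineers who want to assess
the conversion of organic municipal solid waste (OMSW) into volatile
fatty acids (VFAs) and biogas. It implements, as one tested pipeline:

* **BMP kinetics** — biochemical methane potential bottle data: k-NN
  imputation of sparse gas-composition days, inoculum blank correction,
  replicate aggregation, and multi-start nonlinear least-squares fits of
  the first-order model *B(t) = B₀(1 − e^(−kt))* and the modified
  Gompertz model *B(t) = B₀ exp{−exp[(Rₘe/B₀)(λ − t) + 1]}*, plus
  SMP/SGP/biogas-yield/max-CH₄ summaries.
* **Fermentation statistics** — COD solubilization, VFA yield (COD and
  acid-mass bases), ammonia/phosphate release, VFA/SCOD ratio, VFA
  weight-ratio spectrum, stability, and a paired two-tailed t test
  checked against an independent oracle.
* **Flowsheet** — a steady-state mass balance of two plant scenarios for
  70,000 population equivalents: (1) screw press → alkaline-thermal
  pretreatment → mesophilic acidogenic fermentation → separation →
  biochar-amended anaerobic digestion; (2) single-step anaerobic
  digestion. Every unit closes its mass balance to 1e-6 relative.
* **Energy & economics** — stream heating, reactor wall losses, CHP
  conversion, and an undiscounted payback comparison.
* **Synthetic data** — seeded generators that emulate the pilot BMP and
  fermenter experiments, so the whole chain is testable offline.

See `vignette("biovalor-methods")` for the models, assumptions and
calibrated defaults.

## Worked example

Fit the first-order model to a noiseless curve generated at the
no-biochar condition (B₀ = 0.204 Nm³ CH₄/kg-VS, k = 0.57 1/d), then run
and compare the two plant scenarios:

```r
library(biovalor)

t <- 0:25
b <- first_order_curve(t, b0 = 0.204, k = 0.57)
fit_model(t, b, "first_order")
#> Kinetic fit: first_order
#>   b0 = 0.204 Nm3/kg-VS, k = 0.57 1/d
#>   rmse = 2.965e-11 (n = 26, converged = TRUE)

cmp <- compare_scenarios()
cmp$comparison[, c("scenario", "capex_eur", "net_income_eur",
                   "payback_years", "surplus_mj_day")]
#>   scenario capex_eur net_income_eur payback_years surplus_mj_day
#> 1        1    809000      540229.53      1.497512       2851.485
#> 2        2   1618000       38608.91     41.907420      26707.556

res <- cmp$scenario1$result
res$streams$fermenter_feed
#> Stream: 113788 kg/d, TS 4.11%, VS 3.10%, SCOD 0.0 g/L, VFA 0.0 g/L, 21.6 degC
res$units
#>        unit       hrt      olr
#> 1 fermenter  4.499596 6.889508
#> 2  digester 20.022002 6.250000
```

Reading the numbers: the fitter recovers the generating rate constant
exactly (RMSE ~1e-11). Under default prices the multistep line pays back
its EUR 809,000 capital in ~1.5 years because the VFA product (3501
kg-SCOD/day at 0.5 EUR/kg) dwarfs the electricity revenue, while
single-step digestion — despite a much larger energy surplus
(~26,700 vs ~2,850 MJ/day) — needs ~42 years. The fermenter runs at an
HRT of 4.5 days and an OLR of 6.89 kg-VS/m³/day; the scenario-1 digester
at 20 days and 6.25 kg-VS/m³/day.

## Command line

```sh
Rscript inst/scripts/biovalor.R synth bmp --seed 1 --out out/
Rscript inst/scripts/biovalor.R bmp-fit --input out/bmp.csv --out out/
Rscript inst/scripts/biovalor.R scenario --scenario 1 --out out/
Rscript inst/scripts/biovalor.R compare --out out/
```

(After installation the wrapper lives at
`system.file("scripts", "biovalor.R", package = "biovalor")`.)

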