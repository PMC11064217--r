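# paleotp

Reconstructs multi-century **lake-water total phosphorus (TP)** histories
from dated sediment-core phosphorus records, and validates them against
independent proxy records. It is aimed at paleolimnologists and lake
managers who need eutrophication histories far longer than any monitoring
record.

## The method

Sediment-inferred TP (SI-TP) inverts the phosphorus burial record through
the steady-state lake mass balance. With burial flux
`L_sed = C_P × MAR × 10⁴` (mg P m⁻² yr⁻¹), retention coefficient `R_P`
and areal water loading `q_s` (m yr⁻¹):

    TP(t) = L_sed(t) · (1 − R_P) / (R_P · q_s)        [µg L⁻¹]

`R_P` is calibrated locally against a monitored window:
`R_P = L_sed,cal / (L_sed,cal + L_out)` with
`L_out = q_s · mean(monitored TP)`, which **anchors** the modern end of
the inferred record exactly to the monitored mean. Core fluxes are first
corrected for sediment focusing (per-core factors or a lake-geometry
heuristic), and recent samples are corrected for the diagenetic
"stationary peak" with a two-fraction model — a stable fraction plus a
labile fraction decaying as `b·exp(−k·τ)` with burial age `τ` — fitted
per core by bounded multi-start nonlinear least squares and subtracted.

Validation statistics mirror standard proxy–proxy comparison practice:
penalized-spline (GAM) smooths of each irregular record, peak timing,
pairing by means centered on the reference record's dates, OLS with 95%
confidence/prediction intervals and residual normality diagnostics, and
interval-weighted (decadal) means.

A synthetic lake-sediment generator with known ground truth (trajectory,
retention, focusing, diagenetic overprint, noise) makes every stage
testable end to end.

## Worked example

Simulate the default four-core synthetic lake (known truth:
`R_P = 0.75`, TP peaking at 180 µg L⁻¹ in 1930), run both inversion
branches, and compare the corrected record with the synthetic diatom
proxy:

```r
library(paleotp)

sc  <- lake_scenario(seed = 42)
sim <- simulate_lake(sc)
cfg <- sitp_config(2003, 2018, q_s = sc$q_s, focusing = "fixed_factor",
                   focusing_factors = setNames(sc$focusing, names(sim$cores)))
res <- sitp_pipeline(sim$cores, sim$monitoring, cfg, verbose = TRUE)
#> sitp_pipeline: q_s = 2.79 m/yr, L_out = 222.9 mg/m2/yr, window 2003-2018
#>   raw branch:  R_P = 0.8288 (L_sed_cal 1079)
#>   penn branch: R_P = 0.7442 (L_sed_cal 648.4)

run_compare(res$penn, sim$ditp)
#> comparison_report: y = 1.997 x - 3.629, r2 = 0.76, p = 4.49e-12 (n = 36)
#>   GAM peaks: 1926 (paired record) / 1916 (reference); interval-weighted means 71.52 / 220.9 ug/L
```

Reading the output: the uncorrected branch over-retains (`R_P = 0.83`)
because the labile surface pool inflates modern burial; the corrected
branch recovers the true `R_P = 0.75` to within 1%. The comparison
regression recovers the proxy's built-in ×2 bias (slope ≈ 2.0, intercept
indistinguishable from 0) with 76% shared variance, and the GAM peak
lands within a few years of the true 1930 peak despite 10–25% noise.
Interval-weighted means (decadal mean-of-means) summarise each record's
magnitude free of sampling-density artefacts.

The same workflow runs from files via `run_simulate()` / `run_infer()` /
`run_compare()` with a YAML configuration, or from a shell through the
thin wrapper `inst/scripts/paleotp.R` (subcommands `simulate`, `infer`,
`compare`).

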