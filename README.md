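# hccea

A three-state (progression-free → progressed → dead) partitioned-survival
Markov cohort model comparing **FOLFOX4** chemotherapy with **sorafenib** for
advanced hepatocellular carcinoma in the Chinese setting, built for health
economists who want a tested, scriptable re-implementation of this published
comparison — and a reusable two-arm oncology CEA pipeline.

The core quantities:

- **State occupancy** from survivor curves (partitioned survival):
  `PFS(t) = S_pfs(t)`, `Death(t) = 1 − S_os(t)`, `PD(t) = S_os(t) − S_pfs(t)`,
  on a 1-month cycle until cohort extinction.
- **Costs** (US$, direct medical, PFS only — treatment stops at progression):
  BSA-dosed chemotherapy (`BSA = 0.0061·h + 0.0128·w − 0.1529`), per-mg drug
  pricing at 2.14 cycles/month, ward and test schedules, and expected
  adverse-event costs spread over survivors.
- **Engine**: half-cycle (trapezoid) cost and utility accrual, utilities
  0.76 (PFS) / 0.68 (PD) / 0 (death), 5%/year discounting.
- **Comparison**: `ΔC`, `ΔE`, ICER with dominance classification,
  `INHB(λ) = ΔE − ΔC/λ`, `NMB = λE − C`, WHO thresholds ($7358 and $22,073
  per QALY), healthcare-system and patient-copayment perspectives.
- **Uncertainty**: one-way (tornado) analysis and probabilistic sensitivity
  analysis (gamma costs, truncated-normal proportions/utilities/doses,
  survival varied through monthly transition probabilities), CE-plane
  quadrant shares and cost-effectiveness acceptability curves.

Because the source trials published survival only as figures, the package
ships a synthetic exponential curve generator matched to the published
medians (FOLFOX4 OS 6.40 / PFS 2.93 months; sorafenib OS 6.5 months). The
sorafenib PFS median was never published and is a required argument. See the
methods vignette (`vignettes/hcc-cea-model.Rmd`) for what the stand-in curves
do and do not emulate.

## Worked example

```r
library(hccea)
library(dplyr)

model <- cea_model(sorafenib_pfs_median = 2.8)  # user-chosen illustration
base  <- run_cea(model)
glance(base)
#>   cost_folfox4 cost_sorafenib qaly_folfox4 qaly_sorafenib delta_cost
#> 1        9512.         15736.        0.532          0.538     -6223.
#>   delta_effect    icer decision inhb_3x
#> 1     -0.00631 986239. icer       0.276
```

Under the exponential stand-in curves FOLFOX4 saves $6223 per patient;
sorafenib's slightly higher OS median (6.5 vs 6.40 months) gives it a
marginal QALY edge (−0.006), so the result lands as an ICER of ≈ $986k per
QALY *gained by sorafenib* — far beyond the $22,073 willingness-to-pay
threshold, hence the strongly positive incremental net health benefit of
0.276 QALYs for FOLFOX4. (With the trials' actual Kaplan–Meier curves, which
this package cannot reproduce from printed medians, the published analysis
found FOLFOX4 outright dominant.)

```r
one_way(model) |> head(3)
#>   parameter               base   low  high inhb_low inhb_high inhb_base swing
#> 1 sorafenib_monthly_cost  3777  3021  4532    0.139     0.412     0.276 0.273
#> 2 folfox4_monthly_cost    1865  1492  2238    0.346     0.205     0.276 0.141
#> 3 dose_oxaliplatin         138   110   166    0.341     0.210     0.276 0.131

psa <- run_psa(model, master_seed = 1, n_draws = 1000)
ce_plane_quadrants(psa)
#>   quadrant  share
#> 1 dominant  0.353   # FOLFOX4 cheaper and more effective
#> 2 dominated 0.019
#> 3 ne        0.134
#> 4 sw        0.494
ceac(psa, c(7358, 22073))
#>   lambda probability
#> 1   7358       0.872
#> 2  22073       0.909  # P(FOLFOX4 preferred) at 3x GDP per capita
```

Every one-way INHB stays positive and FOLFOX4 is preferred in ~91% of PSA
draws at the 3×GDP threshold. `autoplot()` methods draw the tornado, the CE
plane and the acceptability curve; `cea_report()` writes the full set of CSV
and JSON outputs for a model; `write_synthetic_curves()` /
`read_curve_csv()` exchange curves as `month,os_prop,pfs_prop` CSV so
digitized trial curves can be dropped in.

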