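---
title: "A partitioned-survival Markov model of FOLFOX4 versus sorafenib in advanced HCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned-survival Markov model of FOLFOX4 versus sorafenib in advanced HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccea)
library(dplyr)
```

## The model

`hccea` implements a decision-analytic cohort model comparing two systemic
therapies for advanced hepatocellular carcinoma in the Chinese setting:
FOLFOX4 (oxaliplatin + infusional fluorouracil/leucovorin, one 48-h cycle
every 14 days, administered inpatient) and sorafenib (400 mg orally twice
daily). Patients move through three health states — progression-free survival
(PFS), progressed disease (PD) and death — on a one-month cycle, and are
followed until the whole cohort is dead.

State occupancy is *partitioned survival*: rather than estimating a
transition matrix, the cohort fractions are read directly off the two
survivor curves of each arm,

$$\text{PFS}(t) = S_{pfs}(t), \qquad
  \text{Death}(t) = 1 - S_{os}(t), \qquad
  \text{PD}(t) = S_{os}(t) - S_{pfs}(t).$$

This presumes progression-free patients are a subset of survivors
($S_{pfs} \le S_{os}$, enforced at input and after every perturbation) and
that nobody returns from PD to PFS, consistent with treatment stopping at
progression. Monthly conditional transition probabilities,
$tp(t) = 1 - S(t)/S(t-1)$, are derived only where the sensitivity analyses
need to perturb survival; where a state is exhausted ($S(t-1)=0$) the
probability is defined as 1, a convention that cannot affect results because
occupancy there is zero.

### Synthetic survival curves

The source trials published their survival as figures, not data; the only
numbers available to a re-implementation are the medians (FOLFOX4 OS
6.40 / PFS 2.93 months; sorafenib OS 6.5 months). The package therefore
generates constant-hazard (exponential) stand-ins matched to those medians,
$S(t) = 2^{-t/m}$ on an integer-month grid:

```{r curves}
folfox4 <- make_arm_curves(6.40, 2.93, horizon = 72, arm = "folfox4")
head(folfox4, 4)
```

Exponential is the only family identifiable from a median alone; no shape
information is published. What this stand-in does *not* emulate: the plateau
and step structure of real Kaplan–Meier curves, censoring, and any
non-constant hazard (real OS hazards in advanced HCC typically rise then
fall). Consequently the package's base-case totals and QALYs differ from the
published ones, which were read off the actual trial figures — the tests
validate the *machinery* (occupancy arithmetic, half-cycle accrual,
discounting, incremental algebra) against independent oracles, not the
published headline numbers. The sorafenib PFS median is not published at all,
so `cea_model()` makes it a mandatory argument; examples in this package use
2.8 months as a user-chosen illustration. `binomial_km_noise()` adds
trial-sized binomial sampling noise for fixture realism when needed.

The default horizon is 60 months. With the published medians about 0.15% of
the cohort is still alive there, so curve construction warns and the engine
moves the residue to death one cycle past the horizon — the same convention
the original analysis applied to its single end-of-follow-up survivor. A
72-month horizon silences the warning; results change by well under 0.1%.

### Costs

Direct medical costs (US$) accrue only in PFS, since treatment stops at
progression and only resources differing between arms are modelled:

* **Drugs.** FOLFOX4 doses are body-surface-area based, with
  $BSA = 0.0061\,h_{cm} + 0.0128\,w_{kg} - 0.1529$ and the average Chinese
  adult (161.5 cm, 61.8 kg, BSA 1.62329 m²), giving 138 mg oxaliplatin,
  649 mg leucovorin and 3247 mg fluorouracil per cycle at 2.14 cycles per
  30-day month. Pricing is per-milligram by default (the published monthly
  costs are only reproducible that way); `pricing = "whole_pack"` rounds
  packs up and is never cheaper. Sorafenib is 800 mg/day from a 60 × 200 mg
  pack: the computed $3776/month matches the published $3777 up to
  unit-cost rounding, and the published 5-FU monthly figure ($132 vs a
  computed ~$139) is likewise a rounding artefact we document rather than
  correct.
* **Ward and tests.** The configuration prints $8/day × 5 ward days and a
  $155 test set (2.14 sets/month for FOLFOX4, 1/month for sorafenib). The
  published per-patient ward total is only consistent with roughly $39–40
  per *month*, and the sensitivity table's base is $39/cycle — so the
  model's canonical base ward cost is $39/month, the raw 8 × 5 arithmetic is
  available via `monthly_nondrug_cost()`, and a `ward_per = "cycle"` switch
  exists for the literal reading.
* **Adverse events.** Incidences are whole-trial totals, charged once per
  patient in expectation ($\sum \text{cost} \times \text{incidence}$), with
  nausea/vomiting and AST/ALT elevation billed as one combined cost at the
  higher incidence (they are treated simultaneously). The lump sum is spread
  over cycles proportionally to survivors and conserves the total exactly.
  The published per-patient AE totals ($69/$4) are not reconcilable with any
  parse of the published cost/incidence table (ours implies ~$186/~$31);
  AE parsing choices are documented in the configuration file and AE totals
  are excluded from reproduction checks.

### Engine: half-cycle accrual and discounting

Patients leaving a state are assumed to do so mid-month and accrue half that
month's cost. Arithmetically each cycle charges the trapezoid — the mean of
start- and end-of-cycle occupancy — which is exactly "stayers full month,
movers half". By default the same rule applies to utility accrual
(PFS 0.76, PD 0.68, death 0, annual utilities divided by 12 per cycle), so
QALYs equal utility-weighted life-months when utilities coincide;
`half_cycle_utilities = FALSE` reproduces the stricter literal reading in
which only costs are half-cycled. Whether the original analysis half-cycled
utilities is not stated; both behaviours are provided and the default is the
internally consistent one.

Discounting is 5%/year. The cycle-level timing is not stated either; the
default compounds the annual rate continuously at mid-cycle,
$(1+r)^{-(t-0.5)/12}$, with a `yearly_step` mode available. The two differ
by under 0.5% at these horizons. Cohort arithmetic is on fractions of 1;
the published 1000-patient cohort is a presentation scaling only.

### Comparison and perspectives

`incremental()` reports $\Delta C$, $\Delta E$ and either dominance or the
ICER (a zero $\Delta E$ yields an explicit `"undefined"` marker, never a
division). Net benefit uses the WHO thresholds: GDP per capita $7358 and
3 × GDP, kept at the published $22,073 rather than the arithmetically exact
22,074. The incremental net health benefit is
$INHB(\lambda) = \Delta E - \Delta C/\lambda$.

The patient perspective multiplies each cost component by its copayment
share. The prose rule (25% outpatient drugs/AE, 15% inpatient ward/tests)
contradicts the published patient-perspective totals; those totals are only
reproducible with tests at 25% in both arms, FOLFOX4 drugs+ward at 15%, and
all sorafenib components at 25%. The default `copay_map(..., "reconciled")`
encodes the reconstruction that reproduces the published $1395/$3200;
`"literal"` encodes the sentence as written.

## Sensitivity analysis

`sensitivity_spec()` carries one row per parameter: base, one-way range, SD
and PSA family — gamma for costs (moment-matched, shape $=(\mu/\sigma)^2$),
normal for doses, proportions and utilities. Its base column *is* the model's
base-case parameter vector. The published SD column is internally
inconsistent with the stated 20%/60% rule of thumb; the printed SDs are the
default and `sd_rule = "relative"` regenerates the rule-based ones.

Design choices made where the source was silent or self-contradictory:

* **Survival variation** (80–120%) is applied by dividing both monthly
  transition probabilities of an arm by the factor and rebuilding the curves,
  because the original analysis explicitly varied transition probabilities,
  not medians. Factor > 1 means better survival; the direction is tested.
* **Truncated normals** redraw out-of-domain values (utilities outside
  [0, 1], negative doses) rather than clipping, avoiding point masses at the
  bounds; redraw counts are recorded.
* **Utility ordering in the PSA.** $u_{pfs}$ and $u_{pd}$ are sampled
  independently, so roughly a third of draws have $u_{pd} > u_{pfs}$ given
  the published SDs. We do not reject those draws: rejection would both
  distort the published marginal distributions and exceed any reasonable
  redraw budget. The ordering is enforced on base-case inputs only.
* **Dose vs monthly-cost double counting.** Both the FOLFOX4 monthly cost
  and the per-cycle doses are parameters. The model composes them: the
  monthly drug cost is the sampled monthly-cost parameter times the per-mg
  price-weighted dose ratio relative to base, so in one-way analysis each
  row reproduces its intended perturbation and in the PSA both sources of
  uncertainty enter multiplicatively.
* **Ward fraction and discount rate** vary one-way only (no distribution in
  the source); boundary draws on the CE plane ($\Delta C$ or $\Delta E$
  exactly 0) are never counted as dominant.

`run_psa()` evaluates both arms under each of 1000 joint draws (all
parameters simultaneously, one survival multiplier per arm), and
`ce_plane_quadrants()` / `ceac()` summarise the cloud. The published PSA
shares (63.9% chosen at 3 × GDP, 34.9% dominant, 2.1% dominated) depend on
the digitized trial curves and are not reproducible from medians alone —
with exponential stand-ins the base-case $\Delta E$ can even change sign,
since sorafenib's OS median (6.5) slightly exceeds FOLFOX4's (6.40) while the
published QALY totals favour FOLFOX4. They are therefore documented but not
asserted.

## Numerical conventions and problem sizes

Tolerances: occupancy closure and AE conservation at $10^{-9}$;
curve/transition-probability round trips at $10^{-12}$; Monte-Carlo
comparisons at 3 standard errors. The test suite exercises the cohort engine
against an independent per-patient microsimulation (10⁶ patients on 5-cycle
toys, driven by the transition probabilities with the same half-cycle and
discounting rules), checks the binomial noise generator against the law of
large numbers at n = 10⁷, and verifies that the published FOLFOX4 drug, test
and ward totals all imply the same discounted progression-free duration
(≈ 3.74 months) under the package's costing conventions. PSA determinism is
tested at small draw counts; the full 1000-draw analysis runs in under half
a minute.

## Worked example

```{r example}
model <- suppressWarnings(cea_model(sorafenib_pfs_median = 2.8))
base <- run_cea(model)
glance(base)
tidy(base) |> filter(component == "total")
```

```{r oneway}
tor <- one_way(model)
head(tor, 5)
# autoplot(tor) draws the tornado diagram
```

```{r psa}
psa <- run_psa(model, master_seed = 1, n_draws = 200)
ce_plane_quadrants(psa)
ceac(psa, c(7358, 22073))
# autoplot(psa) draws the CE plane scatter
```

## Limitations

Beyond the synthetic-curve caveat above: no AE disutilities (the source
analysis also omitted them), no dose reductions or treatment interruptions,
no grade-stratified AE costs, no correlation between sampled parameters, no
multi-way frontiers or extended dominance, and all costs in US$ as printed
with no currency conversion. Results are specific to the Chinese pricing and
reimbursement context encoded in the default configuration.
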