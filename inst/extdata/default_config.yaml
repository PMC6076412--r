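# Default model parameterization: Chinese advanced-HCC setting, costs in US$.
# Drug unit costs are hospital-audit / negotiated-list prices; ward, test and
# adverse-event costs come from structured oncologist interviews.
patient:
  height_cm: 161.5
  weight_kg: 61.8
cycles_per_month: 2.14           # one 14-day FOLFOX4 cycle every 30 days
discount:
  annual_rate: 0.05
  mode: annual_compound_monthly
utilities:
  pfs: 0.76
  pd: 0.68
  dead: 0.0
thresholds:
  gdp_per_capita: 7358           # US$, China 2014
  lambda_1x: 7358
  lambda_3x: 22073               # 3 x GDP per capita as printed
arms:
  folfox4:
    os_median: 6.40              # months
    pfs_median: 2.93
    monthly_drug_cost_base: 1865 # US$/month while progression-free
    regimen:
      name: FOLFOX4
      dosing: bsa
      administered_inpatient: true
      components:
        - drug: oxaliplatin
          dose_mg_per_m2: 85     # day 1
          admins_per_cycle: 1
          pack_mg: 50
          pack_cost_usd: 290
        - drug: leucovorin
          dose_mg_per_m2: 200    # days 1 and 2
          admins_per_cycle: 2
          pack_mg: 1225
          pack_cost_usd: 16
        - drug: fluorouracil
          dose_mg_per_m2: 1000   # 400 bolus + 600 infusional, days 1 and 2
          admins_per_cycle: 2
          pack_mg: 400
          pack_cost_usd: 8
    nondrug:
      ward_cost_per_day: 8
      ward_days_per_month: 5     # reconciles ward totals; see package vignette
      test_set_cost: 155
      tests_per_month: 2.14      # once per treatment cycle
  sorafenib:
    os_median: 6.5
    pfs_median: null             # not published; must be supplied by the user
    monthly_drug_cost_base: 3777
    regimen:
      name: sorafenib
      dosing: fixed_daily
      administered_inpatient: false
      components:
        - drug: sorafenib
          daily_mg: 800          # 400 mg twice daily
          pack_tablets: 60
          tablet_mg: 200
          pack_cost_usd: 1888
    nondrug:
      ward_cost_per_day: 0
      ward_days_per_month: 0
      test_set_cost: 155
      tests_per_month: 1         # once per month
# All-grade adverse events (> 10% in either trial arm); costs per event from
# clinician interviews. Nausea/vomiting and abnormal AST/ALT are treated
# simultaneously: one combined cost at the higher of the two incidences.
adverse_events:
  - {name: nausea_vomiting,        cost_usd: 65,  inc_sorafenib: 0.114, inc_folfox4: 0.410, group: gi_hepatic}
  - {name: abnormal_ast_alt,       cost_usd: 59,  inc_sorafenib: 0.000, inc_folfox4: 0.317, group: gi_hepatic}
  - {name: alopecia,               cost_usd: 0,   inc_sorafenib: 0.248, inc_folfox4: 0.000}
  - {name: anorexia,               cost_usd: 26,  inc_sorafenib: 0.128, inc_folfox4: 0.268}
  - {name: bilirubin_elevation,    cost_usd: 349, inc_sorafenib: 0.000, inc_folfox4: 0.202}
  - {name: fatigue,                cost_usd: 3,   inc_sorafenib: 0.201, inc_folfox4: 0.175}
  - {name: diarrhea,               cost_usd: 13,  inc_sorafenib: 0.255, inc_folfox4: 0.159}
  - {name: sensory_neuropathy,     cost_usd: 3,   inc_sorafenib: 0.000, inc_folfox4: 0.153}
  - {name: hfsr,                   cost_usd: 4,   inc_sorafenib: 0.450, inc_folfox4: 0.000}
  - {name: rash,                   cost_usd: 7,   inc_sorafenib: 0.201, inc_folfox4: 0.000}
  - {name: hypertension,           cost_usd: 37,  inc_sorafenib: 0.188, inc_folfox4: 0.000}
  - {name: bone_marrow_suppression, cost_usd: 79, inc_sorafenib: 0.000, inc_folfox4: 0.689}
# Published discounted per-patient component totals (healthcare-system
# perspective) for the base case; used as inputs to the patient-copayment
# perspective reconciliation and to the internal costing cross-check.
reference_totals:
  folfox4:   {drug: 6972,  ward: 145, ae: 69, tests: 1242}
  sorafenib: {drug: 12289, ward: 0,   ae: 4,  tests: 504}
# Patient-copayment proportions. "reconciled" reproduces the published
# patient-perspective totals; "literal" encodes the prose rule (25% outpatient
# drugs/AE, 15% inpatient ward/tests) as written.
copay:
  reconciled:
    folfox4:   {drug: 0.15, ward: 0.15, ae: 0.25, tests: 0.25}
    sorafenib: {drug: 0.25, ward: 0.15, ae: 0.25, tests: 0.25}
  literal:
    folfox4:   {drug: 0.25, ward: 0.15, ae: 0.25, tests: 0.15}
    sorafenib: {drug: 0.25, ward: 0.15, ae: 0.25, tests: 0.15}
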