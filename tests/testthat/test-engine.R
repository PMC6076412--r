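test_that("discount factors follow the configured timing convention", {
  expect_equal(discount_factor(1:24, 0), rep(1, 24))
  expect_equal(discount_factor(13, 0.05, mode = "yearly_step"), 1 / 1.05)
  expect_equal(discount_factor(1, 0.05, mode = "yearly_step"), 1)
  expect_equal(discount_factor(12.5, 0.05), 1.05^(-1))
  d <- discount_factor(1:60, 0.05)
  expect_true(all(diff(d) < 0))
  expect_error(discount_factor(0, 0.05), class = "hccea_invalid_parameter")
  expect_error(discount_factor(1, -0.1), class = "hccea_invalid_parameter")
})

test_that("half-period allocation charges exiters half a month", {
  # one full month for the 0.5 stayers + half a month for the 0.5 exiters,
  # then half a month for the final 0.5 exiters: exactly one drug-month
  crv <- hccea:::new_arm_curves(0:2, os = c(1, 0.5, 0), pfs = c(1, 0.5, 0), arm = "t")
  occ <- occupancy_from_curves(crv)
  res <- run_cohort(occ, pfs_costs = c(drug = 100, ward = 0, tests = 0),
                    ae_stream = 0, annual_rate = 0)
  expect_equal(res$components$undiscounted[res$components$component == "drug"], 100)

  # instant extinction: every component accrues half of one month
  one <- occupancy_from_curves(
    hccea:::new_arm_curves(0:1, os = c(1, 0), pfs = c(1, 0), arm = "t"))
  r1 <- run_cohort(one, pfs_costs = c(drug = 100, ward = 40, tests = 60),
                   ae_stream = 0, annual_rate = 0)
  expect_equal(r1$components$undiscounted[1:2], c(50, 20))
  expect_equal(r1$qaly[["undiscounted"]], 0.5 * 0.76 / 12)
  expect_equal(r1$life_months, 0.5)
})

test_that("equal utilities reduce QALYs to utility-weighted life-months", {
  crv <- toy_curves()
  occ <- occupancy_from_curves(crv)
  u <- 0.7
  res <- run_cohort(occ, pfs_costs = c(drug = 0, ward = 0, tests = 0),
                    ae_stream = 0,
                    utilities = c(pfs = u, pd = u, dead = 0), annual_rate = 0)
  expect_equal(res$qaly[["undiscounted"]], u / 12 * res$life_months,
               tolerance = 1e-12)
})

test_that("costs scale linearly and do not interact with utilities", {
  occ <- occupancy_from_curves(toy_curves())
  base <- run_cohort(occ, pfs_costs = c(drug = 120, ward = 40, tests = 300),
                     ae_stream = 50)
  scaled <- run_cohort(occ, pfs_costs = c(drug = 360, ward = 120, tests = 900),
                       ae_stream = 150)
  expect_equal(scaled$components$discounted, 3 * base$components$discounted,
               tolerance = 1e-12)
  expect_equal(scaled$qaly, base$qaly, tolerance = 1e-12)

  # total is the sum of its components
  tot <- base$components$discounted[base$components$component == "total"]
  expect_equal(tot, sum(base$components$discounted[base$components$component != "total"]),
               tolerance = 1e-9)
})

test_that("discounting lowers discounted totals only, monotonically in the rate", {
  occ <- occupancy_from_curves(suppressWarnings(make_arm_curves(6.4, 2.93, 60)),
                               close = TRUE)
  costs <- c(drug = 1865, ward = 39, tests = 331.7)
  rates <- c(0, 0.05, 0.1)
  runs <- lapply(rates, function(r) run_cohort(occ, costs, ae_stream = 186,
                                               annual_rate = r))
  disc_tot <- vapply(runs, function(r)
    r$components$discounted[r$components$component == "total"], numeric(1))
  undisc_tot <- vapply(runs, function(r)
    r$components$undiscounted[r$components$component == "total"], numeric(1))
  expect_true(all(diff(disc_tot) < 0))
  expect_equal(undisc_tot, rep(undisc_tot[1], 3), tolerance = 1e-12)
  expect_equal(disc_tot[1], undisc_tot[1], tolerance = 1e-12)
  # discounted never exceeds undiscounted, component by component
  expect_true(all(runs[[2]]$components$discounted <=
                    runs[[2]]$components$undiscounted + 1e-12))
})

test_that("QALY-per-life-year sits between the PD and PFS utilities", {
  occ <- occupancy_from_curves(toy_curves())
  res <- run_cohort(occ, pfs_costs = c(drug = 0, ward = 0, tests = 0),
                    ae_stream = 0, annual_rate = 0)
  ratio <- res$qaly[["undiscounted"]] / (res$life_months / 12)
  expect_gte(ratio, 0.68)
  expect_lte(ratio, 0.76)

  # PD never occupied: ratio is exactly the PFS utility
  eq <- occupancy_from_curves(
    hccea:::new_arm_curves(0:3, os = c(1, .6, .3, 0), pfs = c(1, .6, .3, 0), arm = "t"))
  req <- run_cohort(eq, pfs_costs = c(drug = 0, ward = 0, tests = 0),
                    ae_stream = 0, annual_rate = 0)
  expect_equal(req$qaly[["undiscounted"]] / (req$life_months / 12), 0.76,
               tolerance = 1e-12)
})

test_that("the literal costs-only half-cycle reading lowers utility accrual", {
  occ <- occupancy_from_curves(toy_curves())
  full <- run_cohort(occ, pfs_costs = c(drug = 100, ward = 0, tests = 0),
                     ae_stream = 0, half_cycle_utilities = TRUE)
  lit <- run_cohort(occ, pfs_costs = c(drug = 100, ward = 0, tests = 0),
                    ae_stream = 0, half_cycle_utilities = FALSE)
  expect_lt(lit$qaly[["discounted"]], full$qaly[["discounted"]])
  expect_equal(lit$components$discounted, full$components$discounted,
               tolerance = 1e-12)
})

test_that("the cohort engine matches the per-patient microsimulation oracle", {
  crv <- toy_curves()
  occ <- occupancy_from_curves(crv)
  res <- run_cohort(occ, pfs_costs = c(drug = 500, ward = 0, tests = 0),
                    ae_stream = 0, annual_rate = 0.05)
  sim <- oracle_microsim(crv, n = 2e5, seed = 7, pfs_monthly_cost = 500,
                         annual_rate = 0.05)
  drug <- res$components$discounted[res$components$component == "drug"]
  expect_lt(abs(drug - sim$cost_mean), 3 * sim$cost_se)
  expect_lt(abs(res$qaly[["discounted"]] - sim$qaly_mean), 3 * sim$qaly_se)
  expect_lt(abs(res$life_months - sim$life_mean), 3 * sim$life_se)
})
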