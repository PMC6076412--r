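model <- suppressWarnings(cea_model(sorafenib_pfs_median = 2.8))

test_that("parameter draws match the specified moments, domains and seed contract", {
  spec <- sensitivity_spec()
  d1 <- draw_parameters(spec, master_seed = 42, n_draws = 500)
  d2 <- draw_parameters(spec, master_seed = 42, n_draws = 500)
  expect_identical(d1, d2)

  big <- draw_parameters(spec, master_seed = 1, n_draws = 1e5)
  # gamma moment matching: FOLFOX4 monthly cost, mean 1865, sd 373
  expect_equal(mean(big$folfox4_monthly_cost), 1865, tolerance = 0.01)
  expect_equal(sd(big$folfox4_monthly_cost), 373, tolerance = 0.03)
  expect_true(all(big$folfox4_monthly_cost > 0))
  # truncated normal utilities stay in [0, 1]
  expect_true(all(big$utility_pfs >= 0 & big$utility_pfs <= 1))
  expect_true(all(big$utility_pd >= 0 & big$utility_pd <= 1))
  expect_true(all(big$folfox4_survival > 0))
  # non-sampled parameters stay at base
  expect_true(all(big$discount_rate == 0.05))

  degen <- spec |> dplyr::mutate(sd = ifelse(.data$distribution == "none", sd, 0))
  dd <- draw_parameters(degen, master_seed = 5, n_draws = 10)
  expect_true(all(dd$utility_pfs == 0.76))
  expect_true(all(dd$sorafenib_monthly_cost == 3777))
})

test_that("relative SD rule applies 20% to therapy and 60% to non-therapy parameters", {
  rel <- sensitivity_spec(sd_rule = "relative")
  expect_equal(rel$sd[rel$parameter == "folfox4_monthly_cost"], 0.2 * 1865)
  expect_equal(rel$sd[rel$parameter == "test_cost"], 0.6 * 155)
  expect_true(is.na(rel$sd[rel$parameter == "discount_rate"]))
})

test_that("one-way analysis brackets the base case and orders by swing", {
  tor <- one_way(model)
  expect_s3_class(tor, "cea_tornado")
  expect_equal(nrow(tor), nrow(sensitivity_spec()))
  expect_true(all(diff(tor$swing) <= 1e-12))

  # endpoints bracket the base INHB whenever the response is monotone
  brackets <- pmin(tor$inhb_low, tor$inhb_high) <= tor$inhb_base + 1e-9 &
    pmax(tor$inhb_low, tor$inhb_high) >= tor$inhb_base - 1e-9
  expect_true(all(brackets))

  # degenerate range: low = high = base pins INHB to the base case
  flat <- sensitivity_spec() |>
    dplyr::filter(.data$parameter == "test_cost") |>
    dplyr::mutate(low = .data$base, high = .data$base)
  tflat <- one_way(model, spec = flat)
  expect_equal(tflat$inhb_low, tflat$inhb_base, tolerance = 1e-12)
  expect_equal(tflat$inhb_high, tflat$inhb_base, tolerance = 1e-12)

  # dearer comparator drug strictly favours the intervention
  row <- tor[tor$parameter == "sorafenib_monthly_cost", ]
  expect_gt(row$inhb_high, row$inhb_base)
  expect_gt(row$inhb_base, row$inhb_low)

  bogus <- dplyr::tibble(parameter = "no_such_input", base = 1, low = 0, high = 2,
                         sd = NA_real_, distribution = "none")
  expect_error(one_way(model, spec = bogus), class = "hccea_config_error")
})

test_that("PSA is seed-stable and collapses to the base case as all SDs vanish", {
  p1 <- run_psa(model, master_seed = 11, n_draws = 40)
  p2 <- run_psa(model, master_seed = 11, n_draws = 40)
  expect_equal(p1, p2, tolerance = 1e-15)

  degen <- sensitivity_spec() |>
    dplyr::mutate(sd = ifelse(.data$distribution == "none", sd, 0))
  pd <- run_psa(model, spec = degen, master_seed = 3, n_draws = 5)
  base <- glance(run_cea(model))
  expect_equal(pd$delta_cost, rep(base$delta_cost, 5), tolerance = 1e-12)
  expect_equal(pd$delta_effect, rep(base$delta_effect, 5), tolerance = 1e-12)

  expect_error(run_psa(model, n_draws = 0), class = "hccea_invalid_parameter")
})

test_that("a single varying cost parameter propagates its SD into delta cost", {
  only_sor <- sensitivity_spec() |>
    dplyr::mutate(sd = ifelse(.data$parameter == "sorafenib_monthly_cost", sd, 0))
  p <- run_psa(model, spec = only_sor, master_seed = 21, n_draws = 400)
  # delta_cost = const - monthly_cost * discounted sorafenib PFS months
  base <- run_cea(model)
  months <- base$arms$sorafenib$components$discounted[
    base$arms$sorafenib$components$component == "drug"] / 3777
  expect_equal(sd(p$delta_cost), 1126 * months, tolerance = 0.15)
})

test_that("CE-plane quadrant shares partition the draws with boundary rules", {
  hand <- dplyr::tibble(
    delta_effect = c(1, 2, 0.5, -1, -2, 1, 0, -0.5, 0.2, -0.1),
    delta_cost = c(-1, -2, -0.5, 1, 0.5, 2, -3, -1, 0, 0)
  )
  q <- ce_plane_quadrants(hand)
  expect_equal(sum(q$share), 1)
  expect_equal(q$share[q$quadrant == "dominant"], 0.3)
  expect_equal(q$share[q$quadrant == "dominated"], 0.2)
  # boundary draws (zero delta) are never dominant/dominated
  expect_equal(q$share[q$quadrant == "ne"], 0.2)  # (1,2) NE and (0.2,0), (0,-3)->sw
  expect_error(ce_plane_quadrants(hand[0, ]), class = "hccea_invalid_parameter")

  all_dom <- dplyr::tibble(delta_effect = rep(1, 4), delta_cost = rep(-1, 4))
  expect_equal(ce_plane_quadrants(all_dom)$share, c(1, 0, 0, 0))

  p <- run_psa(model, master_seed = 2, n_draws = 60)
  expect_equal(sum(ce_plane_quadrants(p)$share), 1, tolerance = 1e-12)
})

test_that("the acceptability curve matches INHB signs and its asymptotic limits", {
  hand <- dplyr::tibble(delta_effect = c(0.1, 0.1), delta_cost = c(1000, 3000))
  expect_equal(ceac(hand, 20000)$probability, 0.5)

  all_dom <- dplyr::tibble(delta_effect = rep(1, 5), delta_cost = rep(-1, 5))
  expect_equal(ceac(all_dom, c(1, 1e3, 1e6))$probability, rep(1, 3))

  p <- run_psa(model, master_seed = 8, n_draws = 80)
  cc <- ceac(p, c(1e-6, 22073, 1e12))
  expect_equal(cc$probability[1], mean(p$delta_cost < 0), tolerance = 1e-12)
  expect_equal(cc$probability[3], mean(p$delta_effect > 0), tolerance = 1e-12)
  # CEAC at lambda = 1 - share of draws with INHB <= 0
  expect_equal(cc$probability[2],
               1 - mean(inhb(p$delta_effect, p$delta_cost, 22073) <= 0))

  expect_error(ceac(p, numeric(0)), class = "hccea_invalid_parameter")
  expect_error(ceac(p, c(-1, 10)), class = "hccea_invalid_parameter")
})
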