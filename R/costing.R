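#' Body surface area from height and weight
#'
#' Linear BSA formula used for chemotherapy dosing in the Chinese setting:
#' \eqn{BSA = 0.0061 \cdot height_{cm} + 0.0128 \cdot weight_{kg} - 0.1529}.
#' The model's reference patient is the average Chinese adult (161.5 cm,
#' 61.8 kg), giving 1.62329 m^2.
#'
#' @param height_cm,weight_kg Positive numerics (vectorized).
#' @return BSA in m^2.
#' @examples
#' bsa(161.5, 61.8)
#' @export
bsa <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    abort_invalid("`height_cm` and `weight_kg` must be positive and finite.")
  }
  out <- 0.0061 * height_cm + 0.0128 * weight_kg - 0.1529
  if (any(out <= 0)) {
    abort_invalid("computed body surface area is non-positive; check height and weight.")
  }
  out
}

as_regimen <- function(x) {
  if (!is.list(x) || is.null(x$dosing) || is.null(x$components)) {
    abort_config("a regimen must be a list with `dosing` and `components`.")
  }
  x
}

#' Per-cycle drug doses for a regimen
#'
#' For BSA-dosed regimens, each component's dose is
#' `dose_mg_per_m2 * BSA * admins_per_cycle`, reported rounded to the nearest
#' milligram with the unrounded value retained alongside. For fixed-daily
#' regimens (sorafenib) the "cycle" is one 30-day month.
#'
#' @param regimen A regimen list (see the packaged default configuration).
#' @param height_cm,weight_kg Patient dimensions for BSA dosing.
#' @return A tibble with columns `drug`, `mg_exact`, `mg` (rounded).
#' @examples
#' cfg <- default_config()
#' per_cycle_doses(cfg$arms$folfox4$regimen, 161.5, 61.8)
#' @export
per_cycle_doses <- function(regimen, height_cm, weight_kg) {
  regimen <- as_regimen(regimen)
  comp <- purrr::map_dfr(regimen$components, as_tibble)
  if (identical(regimen$dosing, "bsa")) {
    surface <- bsa(height_cm, weight_kg)
    mg <- comp$dose_mg_per_m2 * surface * comp$admins_per_cycle
  } else if (identical(regimen$dosing, "fixed_daily")) {
    mg <- comp$daily_mg * 30
  } else {
    abort_config(sprintf("unknown dosing scheme '%s'.", regimen$dosing))
  }
  tibble(drug = comp$drug, mg_exact = mg, mg = round(mg))
}

#' Monthly drug acquisition cost while progression-free
#'
#' Default `"proportional"` pricing charges drugs per milligram
#' (`pack_cost * mg_needed / pack_mg`), which is how the published monthly
#' costs were constructed; `"whole_pack"` rounds packs up per cycle and is
#' never cheaper. BSA-dosed regimens accrue `cycles_per_month` cycles per
#' 30-day month; fixed-daily regimens accrue 30 days of tablets.
#'
#' @inheritParams per_cycle_doses
#' @param pricing `"proportional"` (default) or `"whole_pack"`.
#' @param cycles_per_month Treatment cycles per 30-day month (default 2.14:
#'   one 48-h treatment cycle every 14 days).
#' @return Cost in US$ per month spent in the progression-free state.
#' @examples
#' cfg <- default_config()
#' monthly_drug_cost(cfg$arms$sorafenib$regimen, 161.5, 61.8)
#' @export
monthly_drug_cost <- function(regimen, height_cm, weight_kg,
                              pricing = c("proportional", "whole_pack"),
                              cycles_per_month = 2.14) {
  pricing <- tryCatch(match.arg(pricing),
                      error = function(e) abort_config("`pricing` must be 'proportional' or 'whole_pack'."))
  regimen <- as_regimen(regimen)
  comp <- purrr::map_dfr(regimen$components, as_tibble)
  if (identical(regimen$dosing, "fixed_daily")) {
    tablets_per_month <- comp$daily_mg / comp$tablet_mg * 30
    if (pricing == "proportional") {
      return(sum(comp$pack_cost_usd * tablets_per_month / comp$pack_tablets))
    }
    return(sum(comp$pack_cost_usd * ceiling(tablets_per_month / comp$pack_tablets)))
  }
  doses <- per_cycle_doses(regimen, height_cm, weight_kg)
  if (pricing == "proportional") {
    per_cycle <- sum(comp$pack_cost_usd * doses$mg_exact / comp$pack_mg)
  } else {
    per_cycle <- sum(comp$pack_cost_usd * ceiling(doses$mg_exact / comp$pack_mg))
  }
  per_cycle * cycles_per_month
}

#' Monthly non-drug costs (ward and tests) while progression-free
#'
#' Ward cost accrues per hospital day; tests accrue per test set. With
#' `ward_per = "month"` (default) the configured ward days are billed once per
#' 30-day month, the convention that reconciles the published per-patient ward
#' totals; `ward_per = "cycle"` bills them every treatment cycle instead.
#'
#' @param schedule A list with `ward_cost_per_day`, `ward_days_per_month`,
#'   `test_set_cost`, `tests_per_month`.
#' @param ward_per `"month"` or `"cycle"`.
#' @param cycles_per_month Used only when `ward_per = "cycle"`.
#' @return Named numeric `c(ward = , tests = )`, US$ per month in PFS.
#' @export
monthly_nondrug_cost <- function(schedule, ward_per = c("month", "cycle"),
                                 cycles_per_month = 2.14) {
  ward_per <- match.arg(ward_per)
  vals <- unlist(schedule[c("ward_cost_per_day", "ward_days_per_month",
                            "test_set_cost", "tests_per_month")])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_invalid("non-drug schedule entries must be non-negative numbers.")
  }
  ward <- schedule$ward_cost_per_day * schedule$ward_days_per_month
  if (ward_per == "cycle") {
    ward <- ward * cycles_per_month
  }
  c(ward = ward, tests = schedule$test_set_cost * schedule$tests_per_month)
}

#' Expected per-patient adverse-event cost
#'
#' Adverse-event incidences are whole-trial-period totals, charged once per
#' patient in expectation: the total is the sum over billing items of
#' `cost * incidence`. Items sharing a `group` label are treated
#' simultaneously, so the group bills a single combined cost (sum of member
#' costs) at the highest member incidence.
#'
#' @param ae_profile A tibble/data frame with columns `cost` (US$/event),
#'   `incidence` (proportion in \[0, 1\]) and optionally `group` (NA for
#'   ungrouped items).
#' @return Expected US$ per patient (undiscounted lump sum).
#' @examples
#' ae_expected_cost(data.frame(cost = c(10, 20), incidence = c(0.5, 0.2)))
#' @export
ae_expected_cost <- function(ae_profile) {
  ae <- as_tibble(ae_profile)
  if (nrow(ae) == 0L) {
    return(0)
  }
  if (any(ae$incidence < 0 | ae$incidence > 1) || any(ae$cost < 0)) {
    abort_invalid("adverse-event incidences must be in [0, 1] and costs non-negative.")
  }
  if (!"group" %in% names(ae)) {
    ae$group <- NA_character_
  }
  ae |>
    mutate(.bill = ifelse(is.na(.data$group),
                          paste0(".item_", dplyr::row_number()), .data$group)) |>
    group_by(.data$.bill) |>
    summarise(cost = sum(.data$cost), incidence = max(.data$incidence),
              .groups = "drop") |>
    summarise(total = sum(.data$cost * .data$incidence)) |>
    dplyr::pull(.data$total)
}

#' Spread a lump adverse-event cost over the cohort trace
#'
#' The trial-period AE cost is allocated across cycles proportionally to the
#' number of patients still alive: `alloc(t) = total * alive(t) / sum(alive)`,
#' with `alive(t) = 1 - dead(t)` for cycles t >= 1. The allocation conserves
#' the total exactly. If the whole cohort is dead from the first cycle the
#' entire cost is charged in cycle 1.
#'
#' @param total_ae_cost Non-negative lump cost, US$ per patient.
#' @param occupancy A `state_occupancy` trace.
#' @return Numeric vector of per-cycle US$ for cycles 1..T.
#' @export
ae_monthly_allocation <- function(total_ae_cost, occupancy) {
  if (!is_scalar_number(total_ae_cost) || total_ae_cost < 0) {
    abort_invalid("`total_ae_cost` must be a single non-negative number.")
  }
  alive <- (1 - occupancy$dead)[-1]
  if (sum(alive) == 0) {
    out <- numeric(length(alive))
    out[1] <- total_ae_cost
    return(out)
  }
  total_ae_cost * alive / sum(alive)
}
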