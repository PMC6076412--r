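#' Per-cycle discount factor
#'
#' Costs and QALYs are discounted at an annual rate (default 5%, per Chinese
#' pharmacoeconomic guidelines). The default mode compounds the annual rate
#' continuously across months and evaluates it at mid-cycle,
#' \eqn{(1+r)^{-(t-0.5)/12}}; `"yearly_step"` applies one step per completed
#' model year, \eqn{(1+r)^{-\lfloor (t-1)/12 \rfloor}}. The two differ by
#' under half a percent at this model's horizons.
#'
#' @param t Cycle index (months, >= 1; vectorized).
#' @param annual_rate Annual discount rate (>= 0).
#' @param mode `"annual_compound_monthly"` (default) or `"yearly_step"`.
#' @return Discount factors in (0, 1].
#' @examples
#' discount_factor(1:12, 0.05)
#' @export
discount_factor <- function(t, annual_rate = 0.05,
                            mode = c("annual_compound_monthly", "yearly_step")) {
  mode <- match.arg(mode)
  if (!is.numeric(annual_rate) || annual_rate < 0) {
    abort_invalid("`annual_rate` must be a non-negative number.")
  }
  if (any(t < 1)) {
    abort_invalid("cycle index `t` must be >= 1.")
  }
  switch(mode,
    annual_compound_monthly = (1 + annual_rate)^(-(t - 0.5) / 12),
    yearly_step = (1 + annual_rate)^(-floor((t - 1) / 12))
  )
}

new_econ_result <- function(components, qaly, life_months, arm = "arm") {
  out <- list(components = components, qaly = qaly, life_months = life_months,
              arm = arm)
  class(out) <- "econ_result"
  out
}

#' Run the discounted cohort trace for one arm
#'
#' Accrues per-cycle costs and QALYs over a state-occupancy trace. Treatment
#' stops at progression, so drug, ward and test costs accrue only in the
#' progression-free state; the lump adverse-event cost arrives as a
#' pre-computed per-cycle stream (see [ae_monthly_allocation()]). Patients who
#' leave a state are assumed to do so halfway through the month and accrue
#' half that month's cost — equivalently each cycle charges the trapezoid
#' (mean of start- and end-of-cycle occupancy). By default the same half-cycle
#' credit applies to utility accrual so QALYs and life-months are internally
#' consistent; `half_cycle_utilities = FALSE` credits utilities on
#' end-of-cycle occupancy only.
#'
#' @param occupancy A `state_occupancy` trace over months 0..T.
#' @param pfs_costs Named numeric, US$ per month in PFS, components
#'   `c(drug=, ward=, tests=)`.
#' @param ae_stream Per-cycle US$ for cycles 1..T (length T), or a single
#'   lump sum to be allocated by [ae_monthly_allocation()].
#' @param utilities Named numeric `c(pfs=, pd=, dead=)` utilities per year.
#' @param annual_rate,mode Discounting, see [discount_factor()].
#' @param half_cycle_utilities Apply the half-cycle rule to utilities too
#'   (default `TRUE`).
#' @param arm Arm label carried on the result.
#' @return An object of class `econ_result`: `$components` (tibble of
#'   `component`, `undiscounted`, `discounted`, US$/patient), `$qaly` (named,
#'   discounted and undiscounted), `$life_months` (undiscounted mean
#'   survival). [tidy()] and [glance()] methods are provided.
#' @export
run_cohort <- function(occupancy, pfs_costs, ae_stream,
                       utilities = c(pfs = 0.76, pd = 0.68, dead = 0),
                       annual_rate = 0.05,
                       mode = c("annual_compound_monthly", "yearly_step"),
                       half_cycle_utilities = TRUE,
                       arm = "arm") {
  mode <- match.arg(mode)
  n_cycles <- nrow(occupancy) - 1L
  if (n_cycles < 1L) {
    abort_invalid("the occupancy trace must cover at least one cycle.")
  }
  if (length(ae_stream) == 1L) {
    ae_stream <- ae_monthly_allocation(ae_stream, occupancy)
  }
  if (length(ae_stream) != n_cycles) {
    abort_invalid(sprintf(
      "`ae_stream` has %d cycles but the occupancy trace has %d.",
      length(ae_stream), n_cycles))
  }
  for (nm in c("drug", "ward", "tests")) {
    if (is.na(pfs_costs[nm])) {
      abort_invalid(sprintf("`pfs_costs` must contain a '%s' component.", nm))
    }
  }
  if (any(utilities < 0) || any(utilities > 1)) {
    abort_invalid("utilities must lie in [0, 1].")
  }

  pfs <- occupancy$pfs
  pd <- occupancy$pd
  alive <- 1 - occupancy$dead
  t_idx <- seq_len(n_cycles)
  # trapezoid person-time: stayers a full month, exiters/entrants half
  pfs_time <- (pfs[t_idx] + pfs[t_idx + 1L]) / 2
  pd_time <- (pd[t_idx] + pd[t_idx + 1L]) / 2
  alive_time <- (alive[t_idx] + alive[t_idx + 1L]) / 2
  disc <- discount_factor(t_idx, annual_rate, mode)

  comp_undisc <- c(
    drug = sum(pfs_costs[["drug"]] * pfs_time),
    ward = sum(pfs_costs[["ward"]] * pfs_time),
    ae = sum(ae_stream),
    tests = sum(pfs_costs[["tests"]] * pfs_time)
  )
  comp_disc <- c(
    drug = sum(pfs_costs[["drug"]] * pfs_time * disc),
    ward = sum(pfs_costs[["ward"]] * pfs_time * disc),
    ae = sum(ae_stream * disc),
    tests = sum(pfs_costs[["tests"]] * pfs_time * disc)
  )
  if (half_cycle_utilities) {
    q_stream <- (utilities[["pfs"]] * pfs_time + utilities[["pd"]] * pd_time) / 12
  } else {
    q_stream <- (utilities[["pfs"]] * pfs[t_idx + 1L] +
                   utilities[["pd"]] * pd[t_idx + 1L]) / 12
  }

  components <- tibble(
    component = c(names(comp_undisc), "total"),
    undiscounted = unname(c(comp_undisc, sum(comp_undisc))),
    discounted = unname(c(comp_disc, sum(comp_disc)))
  )
  new_econ_result(
    components = components,
    qaly = c(undiscounted = sum(q_stream), discounted = sum(q_stream * disc)),
    life_months = sum(alive_time),
    arm = arm
  )
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result: %s>\n", x$arm))
  cat(sprintf("  discounted total cost: $%.0f; QALYs: %.3f; life-months: %.2f\n",
              x$components$discounted[x$components$component == "total"],
              x$qaly[["discounted"]], x$life_months))
  invisible(x)
}

#' Tidy an arm's economic result
#'
#' @param x An `econ_result`.
#' @param ... Unused.
#' @return A tibble with one row per cost component (`drug`, `ward`, `ae`,
#'   `tests`, `total`) and columns `arm`, `component`, `undiscounted`,
#'   `discounted` (US$/patient).
#' @exportS3Method generics::tidy
tidy.econ_result <- function(x, ...) {
  x$components |> mutate(arm = x$arm, .before = 1)
}

#' One-row summary of an arm's economic result
#'
#' @param x An `econ_result`.
#' @param ... Unused.
#' @return A one-row tibble: `arm`, discounted/undiscounted total cost,
#'   discounted/undiscounted QALYs, undiscounted life-months.
#' @exportS3Method generics::glance
glance.econ_result <- function(x, ...) {
  tot <- x$components |> filter(.data$component == "total")
  tibble(
    arm = x$arm,
    cost_discounted = tot$discounted,
    cost_undiscounted = tot$undiscounted,
    qaly_discounted = x$qaly[["discounted"]],
    qaly_undiscounted = x$qaly[["undiscounted"]],
    life_months = x$life_months
  )
}
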