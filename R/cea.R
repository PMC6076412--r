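econ_totals <- function(res, discounted = TRUE) {
  col <- if (discounted) "discounted" else "undiscounted"
  res$components[[col]][res$components$component == "total"]
}

#' Incremental comparison of two arms
#'
#' Computes incremental cost and effect of the intervention relative to the
#' comparator and classifies the result: the intervention *dominates* when it
#' gains QALYs at lower cost, is *dominated* in the mirror case, and otherwise
#' reports the ICER \eqn{\Delta C / \Delta E}. A zero effect difference yields
#' an explicit `"undefined"` label rather than a division.
#'
#' @param res1 Intervention `econ_result` (or `c(cost=, effect=)`).
#' @param res0 Comparator, same form.
#' @return A one-row tibble of class `icer_result`: `delta_cost`,
#'   `delta_effect`, `icer` (NA under dominance/undefined), `decision` one of
#'   `"intervention_dominates"`, `"comparator_dominates"`, `"icer"`,
#'   `"undefined"`.
#' @export
incremental <- function(res1, res0) {
  as_ce <- function(r) {
    if (inherits(r, "econ_result")) {
      c(cost = econ_totals(r), effect = unname(r$qaly[["discounted"]]))
    } else {
      c(cost = unname(r[["cost"]]), effect = unname(r[["effect"]]))
    }
  }
  a <- as_ce(res1)
  b <- as_ce(res0)
  dc <- a[["cost"]] - b[["cost"]]
  de <- a[["effect"]] - b[["effect"]]
  decision <- if (de > 0 && dc < 0) {
    "intervention_dominates"
  } else if (de < 0 && dc > 0) {
    "comparator_dominates"
  } else if (de == 0) {
    "undefined"
  } else {
    "icer"
  }
  out <- tibble(
    delta_cost = dc,
    delta_effect = de,
    icer = if (decision == "icer") dc / de else NA_real_,
    decision = decision
  )
  class(out) <- c("icer_result", class(out))
  out
}

#' Incremental net health benefit
#'
#' \eqn{INHB(\lambda) = \Delta E - \Delta C / \lambda}, in QALYs, at
#' willingness-to-pay \eqn{\lambda} (US$/QALY). Positive INHB means the
#' intervention is preferred at that threshold.
#'
#' @param delta_effect Incremental QALYs (intervention minus comparator).
#' @param delta_cost Incremental cost, US$.
#' @param lambda Willingness-to-pay, US$/QALY (> 0).
#' @return INHB in QALYs (vectorized over its arguments).
#' @examples
#' inhb(0.034, -4371, 22073)
#' @export
inhb <- function(delta_effect, delta_cost, lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort_invalid("`lambda` must be positive and finite.")
  }
  delta_effect - delta_cost / lambda
}

#' Net monetary benefit
#'
#' \eqn{NMB = \lambda E - C} in US$; the between-arm NMB difference equals
#' \eqn{\lambda \cdot INHB}.
#'
#' @param effect QALYs.
#' @param cost US$.
#' @inheritParams inhb
#' @return NMB in US$ (vectorized).
#' @export
nmb <- function(effect, cost, lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort_invalid("`lambda` must be positive and finite.")
  }
  lambda * effect - cost
}

#' Restrict an economic result to the patient-copayment perspective
#'
#' Multiplies each cost component (discounted and undiscounted) by the
#' patient-borne copay proportion for that component and recomputes totals.
#' QALYs are unchanged.
#'
#' @param res An `econ_result`.
#' @param copay Named proportions `c(drug=, ward=, ae=, tests=)` in \[0, 1\]
#'   (see [copay_map()]).
#' @return A new `econ_result`.
#' @export
apply_perspective <- function(res, copay) {
  if (any(is.na(copay[c("drug", "ward", "ae", "tests")])) ||
      any(copay < 0 | copay > 1)) {
    abort_invalid("`copay` must provide drug, ward, ae and tests proportions in [0, 1].")
  }
  comp <- res$components |> filter(.data$component != "total")
  comp <- comp |>
    mutate(
      undiscounted = unname(.data$undiscounted * copay[.data$component]),
      discounted = unname(.data$discounted * copay[.data$component])
    )
  components <- bind_rows(
    comp,
    tibble(component = "total",
           undiscounted = sum(comp$undiscounted),
           discounted = sum(comp$discounted))
  )
  new_econ_result(components, res$qaly, res$life_months, arm = res$arm)
}
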