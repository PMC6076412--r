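#' State occupancy from partitioned survival curves
#'
#' Converts an arm's OS/PFS survivor curves into the three-state cohort trace
#' of the Markov model under the partitioned-survival assumption:
#' progression-free occupancy equals \eqn{S_{pfs}(t)}, dead equals
#' \eqn{1 - S_{os}(t)}, and progressed disease is the difference
#' \eqn{S_{os}(t) - S_{pfs}(t)}. Per-cycle exits (fraction leaving PFS, and
#' deaths) are first differences of the occupancies.
#'
#' @param curves An `arm_curves` tibble.
#' @param close If `TRUE`, any cohort fraction still alive at the horizon is
#'   moved to death in one extra appended cycle, so the trace ends with the
#'   whole cohort dead (the model follows patients until death).
#' @return A tibble of class `state_occupancy` with columns `month`, `pfs`,
#'   `pd`, `dead`, `exit_pfs`, `deaths`. Occupancies sum to 1 at every month.
#' @examples
#' curves <- make_arm_curves(6.40, 2.93, horizon = 72, arm = "folfox4")
#' occupancy_from_curves(curves)
#' @export
occupancy_from_curves <- function(curves, close = FALSE) {
  validate_arm_curves(curves)
  month <- curves$month
  os <- curves$os
  pfs <- curves$pfs
  if (isTRUE(close) && os[[length(os)]] > 0) {
    month <- c(month, month[[length(month)]] + 1L)
    os <- c(os, 0)
    pfs <- c(pfs, 0)
  }
  out <- tibble(
    month = as.integer(month),
    pfs = pfs,
    pd = os - pfs,
    dead = 1 - os,
    exit_pfs = c(0, -diff(pfs)),
    deaths = c(0, -diff(os))
  )
  class(out) <- c("state_occupancy", class(out))
  out
}

#' Monthly transition probabilities from survivor curves
#'
#' Conditional per-cycle probabilities used by the sensitivity analyses:
#' `tp_pfs_exit(t) = 1 - S_pfs(t)/S_pfs(t-1)` (leaving the progression-free
#' state, to progression or death) and `tp_death(t) = 1 - S_os(t)/S_os(t-1)`.
#' When the denominator is zero the state is exhausted and the probability is
#' defined as 1 (the convention cannot affect costs or QALYs because the
#' occupancy there is zero).
#'
#' @param curves An `arm_curves` tibble.
#' @return A tibble with columns `month` (1..T), `tp_pfs_exit`, `tp_death`.
#' @export
transition_probs <- function(curves) {
  validate_arm_curves(curves)
  os <- curves$os
  pfs <- curves$pfs
  t_idx <- seq_len(length(os) - 1L)
  cond <- function(s) {
    prev <- s[t_idx]
    cur <- s[t_idx + 1L]
    ifelse(prev > 0, 1 - cur / prev, 1)
  }
  tibble(
    month = curves$month[t_idx + 1L],
    tp_pfs_exit = cond(pfs),
    tp_death = cond(os)
  )
}

#' Rebuild survivor curves from monthly transition probabilities
#'
#' Inverse of [transition_probs()]: survivor proportions are cumulative
#' products of the conditional survival `1 - tp`. Round-tripping a valid pair
#' of curves through `transition_probs()` and back reproduces them to
#' floating-point accuracy.
#'
#' @param tp A tibble with columns `month`, `tp_pfs_exit`, `tp_death`
#'   (months 1..T).
#' @param arm Arm label for the rebuilt curves.
#' @return An `arm_curves` tibble over months 0..T.
#' @export
curves_from_probs <- function(tp, arm = "arm") {
  os <- c(1, cumprod(1 - tp$tp_death))
  pfs <- c(1, cumprod(1 - tp$tp_pfs_exit))
  curves <- new_arm_curves(c(tp$month[[1]] - 1L, tp$month), os, pfs, arm)
  validate_arm_curves(curves)
  curves
}

#' Scale an arm's survival via its transition probabilities
#'
#' The sensitivity analyses vary survival by a percentage applied to the
#' monthly transition probabilities of PFS and OS simultaneously. A factor
#' `f > 1` means better survival: every conditional exit/death probability is
#' divided by `f` (and clamped to \[0, 1\]) and the curves are rebuilt from
#' the scaled probabilities. `f = 1` returns the input unchanged.
#'
#' @param curves An `arm_curves` tibble.
#' @param factor Positive survival multiplier (1 = base case).
#' @return An `arm_curves` tibble on the same monthly grid.
#' @examples
#' curves <- make_arm_curves(6.40, 2.93, horizon = 72)
#' better <- apply_survival_multiplier(curves, 1.2)
#' all(better$os >= curves$os)
#' @export
apply_survival_multiplier <- function(curves, factor) {
  check_positive_scalar(factor, "factor")
  validate_arm_curves(curves)
  if (factor == 1) {
    return(curves)
  }
  tp <- transition_probs(curves)
  scaled <- tp |>
    mutate(
      tp_pfs_exit = pmin(pmax(.data$tp_pfs_exit / factor, 0), 1),
      tp_death = pmin(pmax(.data$tp_death / factor, 0), 1)
    )
  tryCatch(
    curves_from_probs(scaled, arm = attr(curves, "arm") %||% "arm"),
    hccea_format_error = function(e) {
      abort(sprintf("survival multiplier %.3g produces an invalid curve pair: %s",
                    factor, conditionMessage(e)),
            class = "hccea_invalid_scenario")
    }
  )
}
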