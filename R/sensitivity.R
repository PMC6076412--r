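#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the model with each parameter at its low and at its high
#' one-way bound (all other parameters at base) and reports the incremental
#' net health benefit at the chosen willingness-to-pay threshold. Rows are
#' sorted by the absolute INHB swing, the tornado order.
#'
#' @param model A `cea_model`.
#' @param spec Sensitivity specification (defaults to the model's own).
#' @param lambda Willingness-to-pay, US$/QALY (defaults to the 3x GDP
#'   threshold).
#' @param perspective `"healthcare"` (default) or `"patient"`.
#' @return A tibble of class `cea_tornado`: `parameter`, `base`, `low`,
#'   `high`, `inhb_low`, `inhb_high`, `inhb_base`, `swing`, sorted by
#'   descending `swing`.
#' @export
one_way <- function(model, spec = model$spec, lambda = NULL,
                    perspective = c("healthcare", "patient")) {
  perspective <- match.arg(perspective)
  lambda <- lambda %||% wtp_thresholds(model$config)[["lambda_3x"]]
  unknown <- setdiff(spec$parameter, model$spec$parameter)
  if (length(unknown)) {
    abort_config(sprintf("sensitivity spec targets unknown parameter(s): %s.",
                         paste(unknown, collapse = ", ")))
  }
  inhb_of <- function(overrides) {
    res <- run_cea(model, overrides)
    inc <- if (perspective == "healthcare") res$incremental else res$incremental_patient
    inhb(inc$delta_effect, inc$delta_cost, lambda)
  }
  base_inhb <- inhb_of(list())
  out <- spec |>
    mutate(
      inhb_low = purrr::map2_dbl(.data$parameter, .data$low,
                                 ~ inhb_of(setNames(list(.y), .x))),
      inhb_high = purrr::map2_dbl(.data$parameter, .data$high,
                                  ~ inhb_of(setNames(list(.y), .x))),
      inhb_base = base_inhb,
      swing = abs(.data$inhb_high - .data$inhb_low)
    ) |>
    select("parameter", "base", "low", "high",
           "inhb_low", "inhb_high", "inhb_base", "swing") |>
    arrange(desc(.data$swing))
  attr(out, "lambda") <- lambda
  class(out) <- c("cea_tornado", class(out))
  out
}

#' Draw parameter vectors for probabilistic sensitivity analysis
#'
#' Samples every parameter with a distribution: gamma for costs, matched to
#' (mean, SD) via `shape = (mean/sd)^2`, `scale = sd^2/mean`; normal for
#' proportions, doses and utilities, truncated to the parameter's valid
#' domain (non-negative; utilities in \[0, 1\]; survival multipliers > 0) by
#' redrawing out-of-domain values rather than clipping. `sd = 0` gives
#' constant draws. Parameters with distribution `"none"` stay at base.
#' Reproducible given `master_seed`.
#'
#' @param spec A sensitivity specification, see [sensitivity_spec()].
#' @param master_seed Integer seed driving all draws.
#' @param n_draws Number of parameter vectors (default 1000).
#' @return A tibble with a `draw` column and one column per parameter; the
#'   number of truncation redraws is recorded in attribute `n_redraws`.
#' @export
draw_parameters <- function(spec, master_seed, n_draws = 1000) {
  if (!is_scalar_number(n_draws) || n_draws < 1) {
    abort_invalid("`n_draws` must be a positive integer.")
  }
  n_draws <- as.integer(n_draws)
  redraws <- 0L
  domain_for <- function(p) {
    if (grepl("^utility_", p)) c(0, 1)
    else if (grepl("_survival$", p)) c(1e-12, Inf)
    else c(0, Inf)
  }
  cols <- withr::with_seed(master_seed, {
    purrr::pmap(spec, function(parameter, base, low, high, sd, distribution, ...) {
      if (distribution == "none" || (!is.na(sd) && sd == 0)) {
        return(rep(base, n_draws))
      }
      if (is.na(sd)) {
        abort_config(sprintf("parameter '%s' has distribution '%s' but no SD.",
                             parameter, distribution))
      }
      if (distribution == "gamma") {
        if (base <= 0) {
          abort_config(sprintf("gamma distribution requires a positive base ('%s').", parameter))
        }
        shape <- (base / sd)^2
        rgamma(n_draws, shape = shape, scale = sd^2 / base)
      } else if (distribution == "normal") {
        dom <- domain_for(parameter)
        x <- rnorm(n_draws, base, sd)
        bad <- which(x < dom[1] | x > dom[2])
        while (length(bad)) {
          redraws <<- redraws + length(bad)
          x[bad] <- rnorm(length(bad), base, sd)
          bad <- bad[x[bad] < dom[1] | x[bad] > dom[2]]
        }
        x
      } else {
        abort_config(sprintf("unknown distribution '%s' for parameter '%s'.",
                             distribution, parameter))
      }
    })
  })
  out <- as_tibble(setNames(cols, spec$parameter)) |>
    mutate(draw = dplyr::row_number(), .before = 1)
  attr(out, "n_redraws") <- redraws
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter vectors (all parameters sampled
#' simultaneously; survival variation enters through the monthly transition
#' probabilities of PFS and OS together, one multiplier per arm) and
#' evaluates both arms under each vector, recording per-arm discounted cost
#' and QALYs and the incremental deltas (FOLFOX4 minus sorafenib). Draws that
#' fail model validation are redrawn; a redraw rate above 10% is an error.
#'
#' @param model A `cea_model`.
#' @param spec Sensitivity specification (defaults to the model's own).
#' @param master_seed Integer seed.
#' @param n_draws Number of simulations (default 1000).
#' @return A tibble of class `cea_psa`: `draw`, `cost_folfox4`,
#'   `qaly_folfox4`, `cost_sorafenib`, `qaly_sorafenib`, `delta_cost`,
#'   `delta_effect`. The count of model-validation redraws is in attribute
#'   `n_model_redraws`.
#' @export
run_psa <- function(model, spec = model$spec, master_seed = 1, n_draws = 1000) {
  draws <- draw_parameters(spec, master_seed, n_draws)
  sampled <- spec$parameter[spec$distribution != "none"]
  n_redraws <- 0L
  eval_draw <- function(row) {
    ov <- as.list(row[sampled])
    tryCatch({
      f <- evaluate_arm(model, "folfox4", ov)
      s <- evaluate_arm(model, "sorafenib", ov)
      c(cost_folfox4 = econ_totals(f),
        qaly_folfox4 = unname(f$qaly[["discounted"]]),
        cost_sorafenib = econ_totals(s),
        qaly_sorafenib = unname(s$qaly[["discounted"]]))
    }, hccea_invalid_scenario = function(e) NULL)
  }
  results <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    row <- draws[i, , drop = FALSE]
    val <- eval_draw(row)
    while (is.null(val)) {
      n_redraws <- n_redraws + 1L
      if (n_redraws > 0.1 * n_draws) {
        abort("more than 10% of PSA draws failed model validation.",
              class = "hccea_psa_redraw_error")
      }
      reseed <- as.integer((as.numeric(master_seed) + 104729 * n_redraws) %% 2147483646) + 1L
      row <- draw_parameters(spec, master_seed = reseed, n_draws = 1)
      val <- eval_draw(row)
    }
    results[[i]] <- val
  }
  out <- as_tibble(do.call(rbind, results)) |>
    mutate(
      draw = seq_len(n_draws),
      delta_cost = .data$cost_folfox4 - .data$cost_sorafenib,
      delta_effect = .data$qaly_folfox4 - .data$qaly_sorafenib
    ) |>
    select("draw", dplyr::everything())
  attr(out, "n_model_redraws") <- n_redraws
  class(out) <- c("cea_psa", class(out))
  out
}

#' Cost-effectiveness plane quadrant shares
#'
#' Classifies each PSA draw on the (\eqn{\Delta E}, \eqn{\Delta C}) plane:
#' `dominant` (\eqn{\Delta E > 0, \Delta C < 0}; the intervention gains QALYs
#' and saves money), `dominated` (the mirror image), `ne` (more effective and
#' more costly) and `sw` (less effective and less costly). Draws on a zero
#' boundary are never counted as dominant or dominated: they fall to `ne`
#' when both deltas are >= 0, else to `sw`.
#'
#' @param samples A `cea_psa` tibble (needs `delta_cost`, `delta_effect`).
#' @return A tibble with `quadrant` and `share`; the four shares sum to 1.
#' @export
ce_plane_quadrants <- function(samples) {
  if (nrow(samples) == 0L) {
    abort_invalid("`samples` must contain at least one draw.")
  }
  q <- dplyr::case_when(
    samples$delta_effect > 0 & samples$delta_cost < 0 ~ "dominant",
    samples$delta_effect < 0 & samples$delta_cost > 0 ~ "dominated",
    samples$delta_effect >= 0 & samples$delta_cost >= 0 ~ "ne",
    TRUE ~ "sw"
  )
  tibble(quadrant = c("dominant", "dominated", "ne", "sw")) |>
    mutate(share = purrr::map_dbl(.data$quadrant, ~ mean(q == .x)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the share of PSA draws in which the
#' intervention is preferred, i.e. has strictly positive incremental net
#' health benefit. As \eqn{\lambda \to \infty} the share tends to
#' \eqn{P(\Delta E > 0)}; as \eqn{\lambda \to 0^+}, to
#' \eqn{P(\Delta C < 0)}.
#'
#' @param samples A `cea_psa` tibble.
#' @param lambda_grid Positive willingness-to-pay values, US$/QALY.
#' @return A tibble of class `cea_ceac` with `lambda` and `probability`.
#' @export
ceac <- function(samples, lambda_grid) {
  if (length(lambda_grid) == 0L) {
    abort_invalid("`lambda_grid` must contain at least one threshold.")
  }
  if (any(lambda_grid <= 0)) {
    abort_invalid("`lambda_grid` values must be positive.")
  }
  if (nrow(samples) == 0L) {
    abort_invalid("`samples` must contain at least one draw.")
  }
  out <- tibble(lambda = as.numeric(lambda_grid)) |>
    mutate(probability = purrr::map_dbl(.data$lambda, function(l) {
      mean(inhb(samples$delta_effect, samples$delta_cost, l) > 0)
    }))
  class(out) <- c("cea_ceac", class(out))
  out
}
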