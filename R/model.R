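#' Default sensitivity-analysis specification
#'
#' One row per model parameter with its base value, one-way range, standard
#' deviation and PSA distribution family (`"gamma"` for costs, `"normal"` for
#' proportions, doses and utilities, `"none"` for parameters varied one-way
#' only). The base column is the model's canonical base-case parameter vector.
#' With `sd_rule = "printed"` the SD column holds the published values; with
#' `sd_rule = "relative"` SDs are regenerated from the stated rule of thumb —
#' 20% of base for therapy parameters and 60% for non-therapy cost parameters
#' (ward, AE, tests).
#'
#' @param sd_rule `"printed"` (default) or `"relative"`.
#' @return A tibble with columns `parameter`, `base`, `low`, `high`, `sd`,
#'   `distribution`.
#' @export
sensitivity_spec <- function(sd_rule = c("printed", "relative")) {
  sd_rule <- match.arg(sd_rule)
  spec <- tibble::tribble(
    ~parameter,               ~base,  ~low,   ~high,  ~sd,    ~distribution,
    "folfox4_survival",        1,      0.8,    1.2,    0.20,   "normal",
    "sorafenib_survival",      1,      0.8,    1.2,    0.20,   "normal",
    "sorafenib_monthly_cost",  3777,   3021,   4532,   1126,   "gamma",
    "folfox4_monthly_cost",    1865,   1492,   2238,   373,    "gamma",
    "dose_oxaliplatin",        138,    110,    166,    28,     "normal",
    "dose_fluorouracil",       3247,   2597,   3896,   649,    "normal",
    "dose_leucovorin",         649,    519,    779,    130,    "normal",
    "utility_pfs",             0.76,   0.61,   0.91,   0.152,  "normal",
    "utility_pd",              0.68,   0.54,   0.82,   0.136,  "normal",
    "ward_cost_per_cycle",     39,     19,     78,     8,      "gamma",
    "ae_cost_multiplier",      1,      0.5,    2,      0.20,   "gamma",
    "test_cost",               155,    78,     310,    93,     "gamma",
    "folfox4_ward_fraction",   1,      0.5,    1,      NA,     "none",
    "discount_rate",           0.05,   0,      0.08,   NA,     "none"
  )
  if (sd_rule == "relative") {
    nontherapy <- c("ward_cost_per_cycle", "ae_cost_multiplier", "test_cost")
    spec <- spec |>
      mutate(sd = dplyr::case_when(
        .data$distribution == "none" ~ NA_real_,
        .data$parameter %in% nontherapy ~ 0.6 * .data$base,
        TRUE ~ 0.2 * .data$base
      ))
  }
  spec
}

#' Assemble the two-arm cost-effectiveness model
#'
#' Builds the FOLFOX4-vs-sorafenib model: exponential OS/PFS curves matched to
#' the published medians (or user-supplied curves, e.g. digitized trial
#' curves read with [read_curve_csv()]), the packaged cost/utility
#' configuration, and the sensitivity specification whose base column defines
#' the base-case parameter values. The sorafenib PFS median is not published
#' and therefore has no default: supply `sorafenib_pfs_median` (months) or a
#' full `sorafenib_curves` object.
#'
#' @param sorafenib_pfs_median Median sorafenib PFS in months (required unless
#'   `sorafenib_curves` is given).
#' @param config Model configuration, see [default_config()].
#' @param spec Sensitivity specification, see [sensitivity_spec()].
#' @param horizon Curve horizon in months (default 60).
#' @param folfox4_curves,sorafenib_curves Optional `arm_curves` overriding the
#'   synthetic exponential curves.
#' @param half_cycle_utilities Passed to [run_cohort()].
#' @return An object of class `cea_model`.
#' @examples
#' m <- suppressWarnings(cea_model(sorafenib_pfs_median = 2.8))
#' @export
cea_model <- function(sorafenib_pfs_median = NULL,
                      config = default_config(),
                      spec = sensitivity_spec(),
                      horizon = 60,
                      folfox4_curves = NULL,
                      sorafenib_curves = NULL,
                      half_cycle_utilities = TRUE) {
  if (is.null(folfox4_curves)) {
    folfox4_curves <- make_arm_curves(config$arms$folfox4$os_median,
                                      config$arms$folfox4$pfs_median,
                                      horizon = horizon, arm = "folfox4")
  }
  if (is.null(sorafenib_curves)) {
    if (is.null(sorafenib_pfs_median)) {
      abort_invalid(paste(
        "`sorafenib_pfs_median` is required: the source trial's PFS median is",
        "not published, so no default exists (supply a value or full curves)."))
    }
    sorafenib_curves <- make_arm_curves(config$arms$sorafenib$os_median,
                                        sorafenib_pfs_median,
                                        horizon = horizon, arm = "sorafenib")
  }
  validate_arm_curves(folfox4_curves)
  validate_arm_curves(sorafenib_curves)

  base <- setNames(spec$base, spec$parameter)
  comp <- purrr::map_dfr(config$arms$folfox4$regimen$components, as_tibble)
  structure(
    list(
      config = config,
      spec = spec,
      base_params = base,
      curves = list(folfox4 = folfox4_curves, sorafenib = sorafenib_curves),
      half_cycle_utilities = half_cycle_utilities,
      # constants cached for the sensitivity loops
      ae_base = list(folfox4 = ae_expected_cost(ae_profile(config, "folfox4")),
                     sorafenib = ae_expected_cost(ae_profile(config, "sorafenib"))),
      dose_price_per_mg = setNames(comp$pack_cost_usd / comp$pack_mg, comp$drug)
    ),
    class = "cea_model"
  )
}

#' @export
print.cea_model <- function(x, ...) {
  cat("<cea_model: FOLFOX4 vs sorafenib, three-state partitioned survival>\n")
  cat(sprintf("  horizon: %d months; discount rate: %.1f%%/yr; lambda(3x GDP): $%s/QALY\n",
              max(x$curves$folfox4$month), 100 * x$base_params[["discount_rate"]],
              format(x$config$thresholds$lambda_3x, big.mark = ",")))
  invisible(x)
}

# FOLFOX4 dose-driven drug-cost scale: unit price per mg x dose, relative to
# the base doses, so a dose perturbation rescales the monthly drug cost while
# an untouched dose leaves it at its sampled/base value.
dose_cost_scale <- function(model, ov) {
  price_per_mg <- model$dose_price_per_mg
  ids <- c(oxaliplatin = "dose_oxaliplatin",
           fluorouracil = "dose_fluorouracil",
           leucovorin = "dose_leucovorin")
  base <- model$base_params[ids]
  doses <- vapply(seq_along(ids), function(i) {
    ov[[ids[[i]]]] %||% base[[i]]
  }, numeric(1))
  sum(price_per_mg[names(ids)] * doses) / sum(price_per_mg[names(ids)] * base)
}

param_value <- function(model, ov, id) {
  ov[[id]] %||% model$base_params[[id]]
}

evaluate_arm <- function(model, arm, ov = list()) {
  cfg <- model$config
  mult <- param_value(model, ov, paste0(arm, "_survival"))
  curves <- apply_survival_multiplier(model$curves[[arm]], mult)
  occ <- occupancy_from_curves(curves, close = TRUE)

  drug <- param_value(model, ov, paste0(arm, "_monthly_cost"))
  if (arm == "folfox4") {
    drug <- drug * dose_cost_scale(model, ov)
    ward <- param_value(model, ov, "ward_cost_per_cycle") *
      param_value(model, ov, "folfox4_ward_fraction")
  } else {
    ward <- 0
  }
  tests <- param_value(model, ov, "test_cost") *
    cfg$arms[[arm]]$nondrug$tests_per_month
  ae_total <- model$ae_base[[arm]] * param_value(model, ov, "ae_cost_multiplier")

  run_cohort(
    occupancy = occ,
    pfs_costs = c(drug = drug, ward = ward, tests = tests),
    ae_stream = ae_monthly_allocation(ae_total, occ),
    utilities = c(pfs = param_value(model, ov, "utility_pfs"),
                  pd = param_value(model, ov, "utility_pd"),
                  dead = cfg$utilities$dead),
    annual_rate = param_value(model, ov, "discount_rate"),
    mode = cfg$discount$mode,
    half_cycle_utilities = model$half_cycle_utilities,
    arm = arm
  )
}

#' Run the base case (or a perturbed scenario) of the model
#'
#' Evaluates both arms, compares them incrementally (FOLFOX4 as the
#' intervention, sorafenib as the comparator) and reports INHB at the 1x and
#' 3x GDP willingness-to-pay thresholds, under the healthcare-system
#' perspective and the patient-copayment perspective.
#'
#' @param model A `cea_model`.
#' @param overrides Named list of parameter values replacing entries of the
#'   base parameter vector (names must appear in `model$spec$parameter`).
#' @param copay_type Copay map used for the patient perspective,
#'   see [copay_map()].
#' @return An object of class `cea_result` with elements `arms` (list of
#'   `econ_result`), `patient_arms` (copay-scaled results), `incremental` and
#'   `incremental_patient` (`icer_result` rows), and `inhb` (tibble of INHB at
#'   both thresholds). [tidy()] and [glance()] methods are provided.
#' @examples
#' m <- suppressWarnings(cea_model(sorafenib_pfs_median = 2.8))
#' res <- run_cea(m)
#' glance(res)
#' @export
run_cea <- function(model, overrides = list(),
                    copay_type = c("reconciled", "literal")) {
  copay_type <- match.arg(copay_type)
  unknown <- setdiff(names(overrides), model$spec$parameter)
  if (length(unknown)) {
    abort_config(sprintf("unknown model parameter(s): %s.",
                         paste(unknown, collapse = ", ")))
  }
  arms <- list(
    folfox4 = evaluate_arm(model, "folfox4", overrides),
    sorafenib = evaluate_arm(model, "sorafenib", overrides)
  )
  patient_arms <- purrr::imap(arms, function(res, arm) {
    apply_perspective(res, copay_map(model$config, arm, copay_type))
  })
  inc <- incremental(arms$folfox4, arms$sorafenib)
  inc_p <- incremental(patient_arms$folfox4, patient_arms$sorafenib)
  thr <- wtp_thresholds(model$config)
  inhb_tbl <- tidyr::expand_grid(
    perspective = c("healthcare", "patient"),
    threshold = c("lambda_1x", "lambda_3x")
  ) |>
    mutate(
      lambda = thr[.data$threshold],
      inhb = ifelse(.data$perspective == "healthcare",
                    inhb(inc$delta_effect, inc$delta_cost, .data$lambda),
                    inhb(inc_p$delta_effect, inc_p$delta_cost, .data$lambda))
    )
  structure(
    list(arms = arms, patient_arms = patient_arms,
         incremental = inc, incremental_patient = inc_p,
         inhb = inhb_tbl, lambda = thr[["lambda_3x"]]),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  g <- glance(x)
  cat("<cea_result: FOLFOX4 vs sorafenib>\n")
  cat(sprintf("  FOLFOX4:   $%.0f, %.3f QALYs\n", g$cost_folfox4, g$qaly_folfox4))
  cat(sprintf("  sorafenib: $%.0f, %.3f QALYs\n", g$cost_sorafenib, g$qaly_sorafenib))
  cat(sprintf("  delta cost $%.0f, delta QALY %.3f -> %s\n",
              g$delta_cost, g$delta_effect, g$decision))
  invisible(x)
}

#' Tidy a model run into a long component table
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A tibble keyed by `perspective`, `arm`, `component` with
#'   `undiscounted` and `discounted` US$/patient.
#' @exportS3Method generics::tidy
tidy.cea_result <- function(x, ...) {
  bind_rows(
    purrr::map_dfr(x$arms, tidy) |> mutate(perspective = "healthcare", .before = 1),
    purrr::map_dfr(x$patient_arms, tidy) |> mutate(perspective = "patient", .before = 1)
  )
}

#' One-row summary of a model run (healthcare-system perspective)
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A one-row tibble with per-arm discounted costs and QALYs, the
#'   incremental comparison, and INHB at the 3x GDP threshold.
#' @exportS3Method generics::glance
glance.cea_result <- function(x, ...) {
  tibble(
    cost_folfox4 = econ_totals(x$arms$folfox4),
    cost_sorafenib = econ_totals(x$arms$sorafenib),
    qaly_folfox4 = x$arms$folfox4$qaly[["discounted"]],
    qaly_sorafenib = x$arms$sorafenib$qaly[["discounted"]],
    delta_cost = x$incremental$delta_cost,
    delta_effect = x$incremental$delta_effect,
    icer = x$incremental$icer,
    decision = x$incremental$decision,
    inhb_3x = x$inhb$inhb[x$inhb$perspective == "healthcare" &
                            x$inhb$threshold == "lambda_3x"]
  )
}
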