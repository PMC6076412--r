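#' Packaged default model configuration
#'
#' Loads the shipped YAML configuration: the reference patient, regimens and
#' unit costs, non-drug schedules, the adverse-event table with per-arm
#' incidences and simultaneity groups, utilities, discounting,
#' willingness-to-pay thresholds, copayment maps, and the published
#' discounted component totals used by the patient-perspective reconciliation.
#'
#' @param path Optional path to an alternative YAML file with the same layout.
#' @return A nested list.
#' @examples
#' cfg <- default_config()
#' cfg$cycles_per_month
#' @export
default_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "default_config.yaml", package = "hccea")
  read_config(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("configuration file '%s' does not exist.", path))
  }
  cfg <- yaml::read_yaml(path)
  need <- c("patient", "cycles_per_month", "discount", "utilities",
            "thresholds", "arms", "adverse_events", "copay")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    abort_config(sprintf("configuration is missing key(s): %s.",
                         paste(missing_keys, collapse = ", ")))
  }
  u <- cfg$utilities
  if (!(0 <= u$dead && u$dead <= u$pd && u$pd <= u$pfs && u$pfs <= 1)) {
    abort_config("utilities must satisfy 0 <= dead <= pd <= pfs <= 1.")
  }
  cfg
}

#' Adverse-event profile for one arm
#'
#' Extracts the per-arm billing table (name, cost per event, incidence,
#' simultaneity group) from a configuration.
#'
#' @param config A configuration list from [default_config()].
#' @param arm `"folfox4"` or `"sorafenib"`.
#' @return A tibble with columns `name`, `cost`, `incidence`, `group`.
#' @export
ae_profile <- function(config, arm = c("folfox4", "sorafenib")) {
  arm <- match.arg(arm)
  inc_col <- paste0("inc_", arm)
  purrr::map_dfr(config$adverse_events, function(item) {
    tibble(
      name = item$name,
      cost = item$cost_usd,
      incidence = item[[inc_col]],
      group = item$group %||% NA_character_
    )
  })
}

#' Copayment map for one arm
#'
#' Patient-borne cost proportions per component. The `"reconciled"` map
#' reproduces the published patient-perspective totals (FOLFOX4 drugs and
#' ward at the 15% inpatient rate, tests and AE treatment at 25%, all
#' sorafenib components at 25%); the `"literal"` map encodes the prose rule
#' (25% outpatient drugs/AE, 15% inpatient ward/tests) as written.
#'
#' @inheritParams ae_profile
#' @param type `"reconciled"` (default) or `"literal"`.
#' @return Named numeric proportions `c(drug=, ward=, ae=, tests=)`.
#' @export
copay_map <- function(config, arm = c("folfox4", "sorafenib"),
                      type = c("reconciled", "literal")) {
  arm <- match.arg(arm)
  type <- match.arg(type)
  m <- unlist(config$copay[[type]][[arm]])
  if (any(m < 0 | m > 1)) {
    abort_config("copay proportions must lie in [0, 1].")
  }
  m[c("drug", "ward", "ae", "tests")]
}

#' Willingness-to-pay thresholds
#'
#' WHO-convention thresholds: 1x GDP per capita (highly cost-effective) and
#' 3x GDP per capita (cost-effective). The 3x threshold defaults to the
#' published US$ 22,073.
#'
#' @inheritParams ae_profile
#' @return Named numeric `c(gdp_per_capita=, lambda_1x=, lambda_3x=)` in
#'   US$/QALY.
#' @export
wtp_thresholds <- function(config = default_config()) {
  unlist(config$thresholds)[c("gdp_per_capita", "lambda_1x", "lambda_3x")]
}
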