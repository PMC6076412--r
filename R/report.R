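#' Write synthetic survivor curves to the exchange CSV
#'
#' Convenience wrapper: generates exponential OS/PFS curves matched to the
#' given medians and writes them in the `month,os_prop,pfs_prop` exchange
#' format, echoing the resolved parameters.
#'
#' @param path Output CSV path.
#' @param os_median,pfs_median Medians in months.
#' @param horizon Last month of the grid (default 60).
#' @param arm Arm label.
#' @return `path`, invisibly.
#' @export
write_synthetic_curves <- function(path, os_median, pfs_median,
                                   horizon = 60, arm = "arm") {
  curves <- make_arm_curves(os_median, pfs_median, horizon = horizon, arm = arm)
  inform(sprintf(
    "writing synthetic curves for '%s': OS median %.2f, PFS median %.2f, horizon %d months -> %s",
    arm, os_median, pfs_median, horizon, path))
  write_curve_csv(curves, path)
}

#' Write a full analysis report to a directory
#'
#' Runs the base case and, optionally, the one-way and probabilistic
#' sensitivity analyses, and writes plain-text outputs: `base_case.csv`
#' (long component table, both perspectives), `base_case.json` (per-arm
#' totals, increments, decision, INHB at both thresholds), and when requested
#' `tornado.csv`, `psa_samples.csv`, `ceac.csv` and `quadrants.csv`. Outputs
#' are deterministic given the model and `master_seed`.
#'
#' @param model A `cea_model`.
#' @param out_dir Output directory (created if missing).
#' @param oneway Run the one-way analysis (default `TRUE`).
#' @param n_draws PSA draws; 0 (default) skips the PSA.
#' @param master_seed Seed driving the PSA.
#' @param lambda_grid Thresholds for the acceptability curve.
#' @return Invisibly, a named list of the objects written.
#' @export
cea_report <- function(model, out_dir, oneway = TRUE, n_draws = 0,
                       master_seed = 1,
                       lambda_grid = seq(1000, 60000, by = 1000)) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  base <- run_cea(model)
  readr::write_csv(tidy(base), file.path(out_dir, "base_case.csv"))
  summary_list <- list(
    healthcare = c(
      as.list(glance(base)),
      list(inhb_1x = base$inhb$inhb[base$inhb$perspective == "healthcare" &
                                      base$inhb$threshold == "lambda_1x"])
    ),
    patient = list(
      cost_folfox4 = econ_totals(base$patient_arms$folfox4),
      cost_sorafenib = econ_totals(base$patient_arms$sorafenib),
      delta_cost = base$incremental_patient$delta_cost,
      delta_effect = base$incremental_patient$delta_effect,
      decision = base$incremental_patient$decision
    )
  )
  jsonlite::write_json(summary_list, file.path(out_dir, "base_case.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- list(base_case = base)
  if (isTRUE(oneway)) {
    tor <- one_way(model)
    readr::write_csv(tor, file.path(out_dir, "tornado.csv"))
    out$tornado <- tor
  }
  if (n_draws > 0) {
    psa <- run_psa(model, master_seed = master_seed, n_draws = n_draws)
    readr::write_csv(psa, file.path(out_dir, "psa_samples.csv"))
    readr::write_csv(ce_plane_quadrants(psa), file.path(out_dir, "quadrants.csv"))
    readr::write_csv(ceac(psa, lambda_grid), file.path(out_dir, "ceac.csv"))
    out$psa <- psa
  }
  invisible(out)
}
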