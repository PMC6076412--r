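#' Exponential survivor curve on a monthly grid
#'
#' Builds a parametric stand-in for a trial Kaplan-Meier curve when only the
#' median survival is published: a constant-hazard (exponential) survivor
#' function \eqn{S(t) = \exp(-\ln 2 \cdot t / m)} evaluated at integer months,
#' so that \eqn{S(m) = 0.5} at the median \eqn{m}. Sub-month medians are
#' handled analytically; the grid itself stays at whole months to match the
#' model's one-month cycle.
#'
#' @param median Median survival in months (> 0).
#' @param horizon Last month of the grid (integer >= 1). Default 60 months.
#' @param cycle_length Cycle length in months; only the 1-month cycle used by
#'   the model is supported.
#' @param endpoint `"OS"` or `"PFS"`, carried as metadata.
#' @return A tibble of class `survival_curve` with columns `month` (0..horizon)
#'   and `surv` (survivor proportion), and an `endpoint` attribute.
#' @examples
#' exp_survival_curve(6, horizon = 12)
#' @export
exp_survival_curve <- function(median, horizon = 60, cycle_length = 1,
                               endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  check_positive_scalar(median, "median")
  if (!is_scalar_number(horizon) || horizon < 1 || horizon != round(horizon)) {
    abort_invalid("`horizon` must be a single integer number of months >= 1.")
  }
  if (!identical(as.numeric(cycle_length), 1)) {
    abort_invalid("Only the 1-month cycle length is supported.")
  }
  month <- 0:horizon
  surv <- exp(-log(2) * month / median)
  new_survival_curve(month, surv, endpoint)
}

new_survival_curve <- function(month, surv, endpoint) {
  out <- tibble(month = as.integer(month), surv = as.numeric(surv))
  attr(out, "endpoint") <- endpoint
  class(out) <- c("survival_curve", class(out))
  out
}

#' Validate a survivor curve
#'
#' Checks the defining invariants of a monthly survivor curve: starts at 1,
#' proportions in \[0, 1\], non-increasing over time. Violations raise a
#' format error naming the offending month.
#'
#' @param curve A `survival_curve` or a data frame with `month` and `surv`.
#' @param what Label used in error messages (e.g. `"os_prop"`).
#' @return The input, invisibly, if valid.
#' @export
validate_survival_curve <- function(curve, what = "surv") {
  s <- curve$surv
  m <- curve$month
  if (length(s) < 1L || any(!is.finite(s))) {
    abort_format(sprintf("%s: survivor proportions must be finite.", what))
  }
  if (abs(s[[1]] - 1) > 1e-9) {
    abort_format(sprintf("%s: S(0) must equal 1 (got %.6g).", what, s[[1]]))
  }
  bad <- which(s < -1e-12 | s > 1 + 1e-12)
  if (length(bad)) {
    abort_format(sprintf("%s: proportion out of [0, 1] at month %d.", what, m[bad[[1]]]))
  }
  rise <- which(diff(s) > 1e-12)
  if (length(rise)) {
    abort_format(sprintf("%s rises at month %d; survivor curves must be non-increasing.",
                         what, m[rise[[1]] + 1L]))
  }
  invisible(curve)
}

#' Paired OS/PFS curves for one treatment arm
#'
#' Generates exponential OS and PFS curves matched to published medians for a
#' single arm, on a shared monthly grid. Because progression-free patients are
#' a subset of survivors, the PFS median may not exceed the OS median (under
#' constant hazards this guarantees \eqn{S_{pfs}(t) \le S_{os}(t)} at every
#' month). A warning is emitted when more than 0.1% of the cohort is still
#' alive at the horizon; the cohort engine moves that residue to death one
#' cycle past the horizon.
#'
#' @param os_median,pfs_median Median overall and progression-free survival in
#'   months; `pfs_median <= os_median` is required.
#' @param horizon Last month of the grid (default 60).
#' @param arm Arm label carried as metadata.
#' @return A tibble of class `arm_curves` with columns `month`, `os`, `pfs`
#'   and an `arm` attribute.
#' @examples
#' make_arm_curves(6.40, 2.93, horizon = 72, arm = "folfox4")
#' @export
make_arm_curves <- function(os_median, pfs_median, horizon = 60, arm = "arm") {
  check_positive_scalar(os_median, "os_median")
  check_positive_scalar(pfs_median, "pfs_median")
  if (pfs_median > os_median) {
    abort_invalid("`pfs_median` must not exceed `os_median`: progression-free patients are alive.")
  }
  os <- exp_survival_curve(os_median, horizon, endpoint = "OS")
  pfs <- exp_survival_curve(pfs_median, horizon, endpoint = "PFS")
  out <- new_arm_curves(os$month, os$surv, pfs$surv, arm)
  if (os$surv[[length(os$surv)]] > 0.001) {
    warn(sprintf(
      "%.2f%% of the '%s' cohort is still alive at month %d; consider a longer horizon (survivors are moved to death at month %d).",
      100 * os$surv[[length(os$surv)]], arm, horizon, horizon + 1L))
  }
  out
}

new_arm_curves <- function(month, os, pfs, arm) {
  out <- tibble(month = as.integer(month), os = as.numeric(os), pfs = as.numeric(pfs))
  attr(out, "arm") <- arm
  class(out) <- c("arm_curves", class(out))
  out
}

#' Validate paired arm curves
#'
#' Checks both survivor-curve invariants plus the joint constraint
#' `pfs <= os` at every month.
#'
#' @param curves An `arm_curves` tibble (columns `month`, `os`, `pfs`).
#' @return The input, invisibly, if valid.
#' @export
validate_arm_curves <- function(curves) {
  validate_survival_curve(tibble(month = curves$month, surv = curves$os), "os_prop")
  validate_survival_curve(tibble(month = curves$month, surv = curves$pfs), "pfs_prop")
  bad <- which(curves$pfs > curves$os + 1e-9)
  if (length(bad)) {
    abort_format(sprintf(
      "pfs_prop %.4g exceeds os_prop %.4g at month %d; PFS must be <= OS (progression-free patients are alive).",
      curves$pfs[bad[[1]]], curves$os[bad[[1]]], curves$month[bad[[1]]]))
  }
  invisible(curves)
}

#' Add Kaplan-Meier-style sampling noise to a survivor curve
#'
#' Emulates the sampling variability of a trial of `n_patients`: survivors are
#' thinned month by month with binomial draws whose success probability is the
#' input curve's conditional monthly survival, so the noisy curve matches the
#' input in expectation and is itself a valid (non-increasing) survivor curve.
#'
#' @param curve A `survival_curve` (or data frame with `month`, `surv`).
#' @param n_patients Number of at-risk patients at month 0 (>= 1).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A `survival_curve` with proportions `k/n_patients`.
#' @export
binomial_km_noise <- function(curve, n_patients, seed) {
  validate_survival_curve(curve)
  if (!is_scalar_number(n_patients) || n_patients < 1 || n_patients != round(n_patients)) {
    abort_invalid("`n_patients` must be a single integer >= 1.")
  }
  s <- curve$surv
  withr::with_seed(seed, {
    k <- numeric(length(s))
    k[1] <- n_patients
    for (t in seq_along(s)[-1]) {
      p <- if (s[t - 1] > 0) s[t] / s[t - 1] else 0
      k[t] <- rbinom(1L, size = as.integer(k[t - 1]), prob = min(max(p, 0), 1))
    }
  })
  new_survival_curve(curve$month, k / n_patients,
                     endpoint = attr(curve, "endpoint") %||% "OS")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write the arm-curve exchange CSV
#'
#' The exchange format has columns `month,os_prop,pfs_prop`, month starting at
#' 0 in consecutive integers, proportions as decimals in \[0, 1\]. Reading
#' validates every curve invariant and names the offending row and rule;
#' writing then reading reproduces the values to full stored precision.
#'
#' @param path File path.
#' @param arm Arm label attached to the curves (defaults to the file stem).
#' @return `read_curve_csv()` returns an `arm_curves` tibble;
#'   `write_curve_csv()` returns `path` invisibly.
#' @export
read_curve_csv <- function(path, arm = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("month", "os_prop", "pfs_prop")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_format(sprintf("curve file '%s' is missing column(s): %s.",
                         path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) < 1L || df$month[[1]] != 0 ||
      !all(diff(df$month) == 1)) {
    abort_format("`month` must start at 0 and increase in consecutive integers.")
  }
  curves <- new_arm_curves(df$month, df$os_prop, df$pfs_prop,
                           arm %||% sub("\\.[^.]*$", "", basename(path)))
  validate_arm_curves(curves)
  curves
}

#' @param curves An `arm_curves` tibble to serialize.
#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curves, path) {
  validate_arm_curves(curves)
  out <- tibble(month = curves$month, os_prop = curves$os, pfs_prop = curves$pfs)
  readr::write_csv(out, path)
  invisible(path)
}
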