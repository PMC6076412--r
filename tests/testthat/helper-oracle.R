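# Independent per-patient microsimulation oracle.
#
# Simulates n patients from the monthly transition probabilities of an arm's
# curves: a progression-free process (exit with tp_pfs_exit) and a survival
# process (death with tp_death), simulated as independent chains -- every
# quantity the cohort engine reports is linear in the two marginal traces, so
# any joint law with the right marginals gives the same expectations.
# Per-patient accrual applies the same half-period rule as the engine (a full
# month for a cycle survived, half a month for the cycle of exit) and the
# same discounting; per-patient progressed-disease time is alive-time minus
# progression-free time.
oracle_microsim <- function(curves, n, seed, pfs_monthly_cost = 0,
                            utilities = c(pfs = 0.76, pd = 0.68, dead = 0),
                            annual_rate = 0,
                            mode = "annual_compound_monthly") {
  tp <- hccea::transition_probs(curves)
  n_cycles <- nrow(tp)
  res <- withr::with_seed(seed, {
    pfs_exit <- rep(n_cycles + 1L, n)
    death <- rep(n_cycles + 1L, n)
    in_pfs <- rep(TRUE, n)
    alive <- rep(TRUE, n)
    for (t in seq_len(n_cycles)) {
      ex <- in_pfs & (stats::runif(n) < tp$tp_pfs_exit[t])
      pfs_exit[ex] <- t
      in_pfs[ex] <- FALSE
      di <- alive & (stats::runif(n) < tp$tp_death[t])
      death[di] <- t
      alive[di] <- FALSE
    }
    list(pfs_exit = pfs_exit, death = death)
  })
  tmat <- matrix(rep(seq_len(n_cycles), each = n), nrow = n)
  pfs_time <- (res$pfs_exit > tmat) + 0.5 * (res$pfs_exit == tmat)
  alive_time <- (res$death > tmat) + 0.5 * (res$death == tmat)
  pd_time <- alive_time - pfs_time
  disc <- matrix(rep(hccea::discount_factor(seq_len(n_cycles), annual_rate, mode),
                     each = n), nrow = n)
  cost_i <- rowSums(pfs_time * disc) * pfs_monthly_cost
  qaly_i <- rowSums((utilities[["pfs"]] * pfs_time +
                       utilities[["pd"]] * pd_time) / 12 * disc)
  life_i <- rowSums(alive_time)
  months0 <- matrix(rep(0:n_cycles, each = n), nrow = n)
  list(
    cost_mean = mean(cost_i), cost_se = stats::sd(cost_i) / sqrt(n),
    qaly_mean = mean(qaly_i), qaly_se = stats::sd(qaly_i) / sqrt(n),
    life_mean = mean(life_i), life_se = stats::sd(life_i) / sqrt(n),
    occ_pfs = colMeans(res$pfs_exit > months0),
    occ_alive = colMeans(res$death > months0),
    n = n
  )
}

# 5-cycle toy arm whose cohort is extinct at the horizon (no closing needed).
toy_curves <- function() {
  hccea:::new_arm_curves(
    month = 0:5,
    os = c(1, 0.82, 0.55, 0.31, 0.12, 0),
    pfs = c(1, 0.58, 0.30, 0.14, 0.04, 0),
    arm = "toy"
  )
}

# econ_result with prescribed discounted = undiscounted component totals,
# for testing perspective transforms against published component tables.
econ_from_components <- function(drug, ward, ae, tests, qaly = 0.4, arm = "arm") {
  comp <- tibble::tibble(
    component = c("drug", "ward", "ae", "tests", "total"),
    undiscounted = c(drug, ward, ae, tests, drug + ward + ae + tests),
    discounted = c(drug, ward, ae, tests, drug + ward + ae + tests)
  )
  hccea:::new_econ_result(comp, qaly = c(undiscounted = qaly, discounted = qaly),
                          life_months = 12 * qaly / 0.68, arm = arm)
}
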