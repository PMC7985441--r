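# Cost and QALY accrual rules.
#
# Per cycle, by state (all amounts USD):
#   PFS  induction: sorafenib + tests, plus (combination arm) BSA-scaled
#        FOLFOX drugs + HAIC procedure + the 2-day hospitalization.
#   RFS  surveillance tests only.
#   PD   best supportive care by default (`pd_cost_mode = "bsc"`); or the
#        subsequent-treatment mix applied every PD cycle ("mix").
#   DEAD nothing.
# SAE management costs and utility decrements are charged once, incidence-
# weighted, in cycle 0 -- except hand-foot syndrome, whose cost and
# disutility persist every cycle (across all alive states by default).
# The hepatectomy lump sum is charged to the branching fraction at the
# branch cycle.

#' Discount factor
#'
#' \eqn{(1 + r)^{-t}} with `time` in years; evaluated at cycle start
#' throughout the model (no half-cycle shift unless
#' `settings$half_cycle_correction` is on, which averages adjacent
#' occupancy rows instead of moving the discount grid).
#'
#' @param time time in years (vectorised, non-negative).
#' @param annual_rate annual discount rate (> -1).
#' @return Discount multiplier(s).
#' @export
discount_factor <- function(time, annual_rate) {
  if (any(time < 0)) abort_model("discount_factor: negative time")
  if (annual_rate <= -1) abort_model("discount_factor: rate must exceed -1")
  (1 + annual_rate)^(-time)
}

# BSA scaling applies only to the per-m^2-dosed FOLFOX drugs
bsa_factor <- function(pars) pars$costs$bsa_patient / pars$costs$bsa_reference

folfox_cycle_cost <- function(pars) {
  pc <- pars$costs$per_cycle
  bsa_factor(pars) * (pc$oxaliplatin + pc$fluorouracil + pc$leucovorin)
}

haic_regimen_cycle_cost <- function(pars) {
  pc <- pars$costs$per_cycle
  folfox_cycle_cost(pars) + pc$haic_procedure + pc$hospitalization
}

sae_lump_cost <- function(pars, strategy_id) {
  st <- pars$strategies[[strategy_id]]
  transient <- setdiff(SAE_TYPES, "hfs")
  sum(vapply(transient, function(s)
    st$sae_incidence[[s]] * pars$costs$one_time[[s]], 0))
}

sae_lump_disutility <- function(pars, strategy_id) {
  st <- pars$strategies[[strategy_id]]
  transient <- setdiff(SAE_TYPES, "hfs")
  sum(vapply(transient, function(s)
    st$sae_incidence[[s]] * pars$utilities$disutility[[s]], 0))
}

hfs_cycle_cost <- function(pars, strategy_id) {
  pars$strategies[[strategy_id]]$sae_incidence$hfs * pars$costs$per_cycle$hfs
}

hfs_cycle_disutility <- function(pars, strategy_id) {
  pars$strategies[[strategy_id]]$sae_incidence$hfs * pars$utilities$disutility$hfs
}

pd_cycle_cost <- function(pars, strategy_id) {
  pc <- pars$costs$per_cycle
  if (pars$settings$pd_cost_mode == "bsc") return(pc$bsc)
  mix <- pars$strategies[[strategy_id]]$subsequent_mix
  mix$sorafenib * pc$sorafenib + mix$haic * haic_regimen_cycle_cost(pars) +
    mix$bsc * pc$bsc
}

#' Per-cycle cost of occupying a health state
#'
#' Incidence-weighted SAE lump sums are part of the cycle-0 PFS cost; the
#' persisting hand-foot-syndrome management cost is added to every state in
#' its configured scope (`settings$hfs_scope`, default all alive states).
#' The hepatectomy lump sum is *not* part of any state's per-cycle cost --
#' it is charged by [accrue()] to the fraction that branches.
#'
#' @param state one of `"pfs"`, `"rfs"`, `"pd"`, `"dead"`.
#' @inheritParams strategy_curves
#' @param cycle_index 0-based cycle index.
#' @return Cost in USD for one cycle of full occupancy of `state`.
#' @export
state_cycle_cost <- function(state, pars, strategy_id, cycle_index) {
  if (!state %in% STATES) abort_model(sprintf("unknown health state '%s'", state))
  if (state == "dead") return(0)
  pc <- pars$costs$per_cycle
  st <- pars$strategies[[strategy_id]]
  hfs <- hfs_cycle_cost(pars, strategy_id)
  base <- switch(state,
    pfs = pc$sorafenib + pc$test +
      (if (isTRUE(st$uses_haic)) haic_regimen_cycle_cost(pars) else 0),
    rfs = pc$test,
    pd = pd_cycle_cost(pars, strategy_id))
  if (pars$settings$hfs_scope == "alive" || state == "pfs") base <- base + hfs
  if (state == "pfs" && cycle_index == 0L)
    base <- base + sae_lump_cost(pars, strategy_id)
  base
}

#' Per-cycle quality-adjusted time of occupying a health state
#'
#' Utility weight (0.76 in PFS and RFS, 0.68 in PD by default) times the
#' cycle length in years, minus the persisting hand-foot-syndrome
#' disutility; the transient SAE decrements are applied once at cycle 0 as
#' a one-cycle utility decrement. Clamped at zero.
#'
#' @inheritParams state_cycle_cost
#' @param cycle_years cycle length in years.
#' @return QALYs accrued by one cycle of full occupancy.
#' @export
state_cycle_qaly <- function(state, pars, strategy_id, cycle_index, cycle_years) {
  if (!state %in% STATES) abort_model(sprintf("unknown health state '%s'", state))
  if (state == "dead") return(0)
  u <- switch(state, pfs = , rfs = pars$utilities$pfs, pd = pars$utilities$pd)
  if (pars$settings$hfs_scope == "alive" || state == "pfs")
    u <- u - hfs_cycle_disutility(pars, strategy_id)
  if (state == "pfs" && cycle_index == 0L)
    u <- u - sae_lump_disutility(pars, strategy_id)
  max(u, 0) * cycle_years
}

#' Accrue discounted costs, life-years and QALYs over a cohort trace
#'
#' Sums occupancy x per-cycle value x discount factor at the cycle-start
#' time over all cycles and states, using the accrual rules of
#' [state_cycle_cost()] and [state_cycle_qaly()], and adds the discounted
#' hepatectomy lump sum for the branching fraction. Life-years are
#' discounted at the same rate as QALYs and costs. With
#' `settings$half_cycle_correction` on, each cycle is valued at the mean of
#' its start and end occupancy.
#'
#' @param trace a [run_cohort()] trace.
#' @param pars the same bundle the trace was produced with.
#' @return An object of class `haic_accrual`: `total_cost`, `total_lys`,
#'   `total_qalys` and a per-component cost `breakdown` that sums to
#'   `total_cost`.
#' @export
accrue <- function(trace, pars) {
  if (!inherits(trace, "cohort_trace")) abort_model("trace must be a cohort_trace")
  strategy_id <- trace$strategy_id
  st <- pars$strategies[[strategy_id]]
  if (is.null(st)) abort_model("trace strategy not present in bundle")
  n_cycles <- trace$n_cycles
  if (nrow(trace$occupancy) != n_cycles + 1L)
    abort_model("trace shape does not match its cycle count")
  u_years <- cycle_length_years(pars)
  u_months <- cycle_length_months(pars)
  dr <- pars$settings$discount_rate_annual
  k <- seq_len(n_cycles) - 1L
  disc <- discount_factor(k * u_months / 12, dr)

  occ <- trace$occupancy[k + 1L, , drop = FALSE]
  if (isTRUE(pars$settings$half_cycle_correction))
    occ <- (occ + trace$occupancy[k + 2L, , drop = FALSE]) / 2

  # per-cycle unit costs (constant except the cycle-0 SAE lump)
  pc <- pars$costs$per_cycle
  hfs <- hfs_cycle_cost(pars, strategy_id)
  hfs_states <- if (pars$settings$hfs_scope == "alive") c("pfs", "rfs", "pd") else "pfs"
  induction_drug <- pc$sorafenib + (if (isTRUE(st$uses_haic)) folfox_cycle_cost(pars) else 0)
  procedure <- if (isTRUE(st$uses_haic)) pc$haic_procedure else 0
  hosp <- if (isTRUE(st$uses_haic)) pc$hospitalization else 0
  pd_c <- pd_cycle_cost(pars, strategy_id)

  wpfs <- sum(occ[, "pfs"] * disc)
  wrfs <- sum(occ[, "rfs"] * disc)
  wpd <- sum(occ[, "pd"] * disc)
  walive <- vapply(c(pfs = "pfs", rfs = "rfs", pd = "pd"),
                   function(s) sum(occ[, s] * disc), 0)

  lump_occ <- if (n_cycles >= 1L) occ[1L, "pfs"] else 0
  branch_disc <- discount_factor(trace$branch$cycle * u_months / 12, dr)

  breakdown <- c(
    induction_drugs = induction_drug * wpfs,
    haic_procedure = procedure * wpfs,
    hospitalization = hosp * wpfs,
    tests = pc$test * (wpfs + wrfs),
    progressive_disease = pd_c * wpd,
    sae_management = sae_lump_cost(pars, strategy_id) * lump_occ +
      hfs * sum(walive[hfs_states]),
    hepatectomy = trace$branch$moved * pars$costs$one_time$hepatectomy *
      (if (trace$branch$cycle < n_cycles) branch_disc else 0)
  )

  qaly_pfs <- rep(state_cycle_qaly("pfs", pars, strategy_id, 1L, u_years),
                  length(k))
  if (n_cycles >= 1L)
    qaly_pfs[1L] <- state_cycle_qaly("pfs", pars, strategy_id, 0L, u_years)
  qaly_rfs <- state_cycle_qaly("rfs", pars, strategy_id, 1L, u_years)
  qaly_pd <- state_cycle_qaly("pd", pars, strategy_id, 1L, u_years)

  total_qalys <- sum(disc * (occ[, "pfs"] * qaly_pfs +
                               occ[, "rfs"] * qaly_rfs +
                               occ[, "pd"] * qaly_pd))
  total_lys <- sum(disc * rowSums(occ[, c("pfs", "rfs", "pd"), drop = FALSE])) *
    u_years

  structure(
    list(strategy_id = strategy_id,
         name = st$name,
         total_cost = sum(breakdown),
         total_lys = total_lys,
         total_qalys = total_qalys,
         breakdown = breakdown,
         n_cycles = n_cycles),
    class = "haic_accrual"
  )
}

#' @export
print.haic_accrual <- function(x, ...) {
  cat(sprintf("%s: cost $%.2f | %.4f LYs | %.4f QALYs (discounted, %d cycles)\n",
              x$name, x$total_cost, x$total_lys, x$total_qalys, x$n_cycles))
  invisible(x)
}
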