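# Four-state cohort engine: PFS, RFS (post-hepatectomy), PD, DEAD.
# DEAD is absorbing; no transitions back into PFS, and none from RFS to PFS.

cycle_length_months <- function(pars) pars$settings$cycle_length_days / MONTH_DAYS

cycle_length_years <- function(pars) pars$settings$cycle_length_days / 365.25

#' Effective survival curves of a strategy
#'
#' Returns the PFS and OS Weibull curves actually used by the engine, i.e.
#' after applying the `os_median_calibration` setting: `"scale"` (default)
#' or `"shape"` recalibrate the OS curve to the strategy's trial median OS
#' (`os_target_median_months`) via [calibrate_weibull_median()]; `"none"`
#' uses the configured parameters verbatim.
#'
#' @param pars a `haic_params` bundle.
#' @param strategy_id `"sorahaic"` or `"sorafenib"`.
#' @return List with elements `pfs` and `os`, both [weibull_params()].
#' @export
strategy_curves <- function(pars, strategy_id) {
  st <- pars$strategies[[strategy_id]]
  if (is.null(st)) abort_validation("unknown strategy", strategy_id)
  os <- as_weibull_params(st$os_weibull)
  cal <- pars$settings$os_median_calibration
  if (cal != "none" && !is.null(st$os_target_median_months))
    os <- calibrate_weibull_median(os, st$os_target_median_months, adjust = cal)
  list(pfs = as_weibull_params(st$pfs_weibull), os = os)
}

# per-cycle probability components for cycles (0-based vector)
cycle_probs <- function(pars, strategy_id, cycles) {
  u <- cycle_length_months(pars)
  cv <- strategy_curves(pars, strategy_id)
  p_bg <- annual_to_cycle_probability(pars$mortality$flat_annual_probability, u)
  p_exit <- cycle_transition_probability(cv$pfs, cycles, u)
  p_death <- pmax(cycle_transition_probability(cv$os, cycles, u), p_bg)
  rule <- pars$settings$pfs_death_rule
  if (rule == "os_competing") {
    to_dead <- p_death
    to_pd <- pmin(p_exit, 1 - p_death)
  } else if (rule == "os_excess") {
    to_dead <- p_death
    to_pd <- pmax(0, p_exit - p_death)
  } else { # background
    to_dead <- rep(p_bg, length(cycles))
    to_pd <- pmax(0, p_exit - p_bg)
  }
  p_rec <- probability_from_cumulative_incidence(
    pars$recurrence$cumulative_incidence,
    pars$recurrence$horizon_years * 12, u)
  list(pfs_to_pd = to_pd, pfs_to_dead = to_dead, pd_to_dead = p_death,
       rfs_to_pd = p_rec, rfs_to_dead = p_bg, p_bg = p_bg)
}

#' Build the one-cycle transition matrix
#'
#' Rows and columns are ordered PFS, RFS, PD, DEAD. Exit from PFS is driven
#' by the PFS curve; death in PFS and PD by the OS curve's conditional
#' per-cycle probability, floored by background mortality; RFS faces the
#' recurrence hazard (constant rate derived from the configured cumulative
#' incidence) plus background mortality only. How the PFS row splits between
#' progression and death is governed by `settings$pfs_death_rule`:
#' \describe{
#'   \item{`os_competing` (default)}{PFS->PD is the PFS-curve exit
#'     probability (capped at the residual after death) and PFS->DEAD the OS
#'     conditional probability, applied as competing events.}
#'   \item{`os_excess`}{PFS->PD is the excess of PFS-curve exit over the
#'     death probability, floored at 0 (all-cause PFS exit decomposed into
#'     death plus progression).}
#'   \item{`background`}{only background mortality acts in PFS; all
#'     remaining PFS exit is progression.}
#' }
#' Under the first two rules the pre-hepatectomy cohort's overall survival
#' tracks the OS curve exactly.
#'
#' @inheritParams strategy_curves
#' @param cycle_index 0-based cycle index.
#' @return A 4x4 matrix; rows sum to 1, DEAD is absorbing, and no entries
#'   flow back into PFS.
#' @export
build_transition_matrix <- function(pars, strategy_id, cycle_index) {
  p <- cycle_probs(pars, strategy_id, cycle_index)
  m <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  m["pfs", "pd"] <- p$pfs_to_pd
  m["pfs", "dead"] <- p$pfs_to_dead
  m["pfs", "pfs"] <- 1 - p$pfs_to_pd - p$pfs_to_dead
  m["rfs", "pd"] <- p$rfs_to_pd
  m["rfs", "dead"] <- p$rfs_to_dead
  m["rfs", "rfs"] <- 1 - p$rfs_to_pd - p$rfs_to_dead
  m["pd", "dead"] <- p$pd_to_dead
  m["pd", "pd"] <- 1 - p$pd_to_dead
  m["dead", "dead"] <- 1
  if (any(m < -1e-12) || any(m > 1 + 1e-12))
    abort_model(sprintf(
      "transition probability outside [0, 1] at cycle %d for strategy '%s'",
      cycle_index, strategy_id))
  m
}

#' Move the down-staged fraction from PFS into RFS
#'
#' At the end of induction (default: start of cycle 4) the configured
#' hepatectomy fraction of the patients still progression-free is resected
#' and enters recurrence-free survival. Total occupancy is conserved. Called
#' at any other cycle the row is returned unchanged with a warning.
#'
#' @param state_row named occupancy vector over `c("pfs","rfs","pd","dead")`.
#' @inheritParams strategy_curves
#' @param cycle_index 0-based cycle index at which the call happens.
#' @return The updated occupancy row, with attribute `moved` giving the
#'   occupancy mass transferred.
#' @export
apply_hepatectomy_branch <- function(state_row, pars, strategy_id, cycle_index) {
  branch_cycle <- pars$settings$hepatectomy_branch_cycle
  if (cycle_index != branch_cycle) {
    warning(sprintf("hepatectomy branch requested at cycle %d but configured for cycle %d; no-op",
                    cycle_index, branch_cycle))
    attr(state_row, "moved") <- 0
    return(state_row)
  }
  frac <- pars$strategies[[strategy_id]]$hepatectomy_fraction
  moved <- frac * state_row[["pfs"]]
  state_row[["pfs"]] <- state_row[["pfs"]] - moved
  state_row[["rfs"]] <- state_row[["rfs"]] + moved
  attr(state_row, "moved") <- moved
  state_row
}

# shared recursion; N cycles; optionally stop once DEAD >= stop_at_dead
cohort_recursion <- function(pars, strategy_id, n_cycles, stop_at_dead = NULL) {
  p <- cycle_probs(pars, strategy_id, seq_len(n_cycles) - 1L)
  branch_cycle <- pars$settings$hepatectomy_branch_cycle
  frac <- pars$strategies[[strategy_id]]$hepatectomy_fraction
  occ <- matrix(0, n_cycles + 1L, 4L, dimnames = list(NULL, STATES))
  occ[1L, ] <- c(1, 0, 0, 0)
  cur <- occ[1L, ]
  moved <- 0
  reached <- n_cycles
  for (k in seq_len(n_cycles) - 1L) {
    if (k == branch_cycle) {
      moved <- frac * cur[["pfs"]]
      cur[["pfs"]] <- cur[["pfs"]] - moved
      cur[["rfs"]] <- cur[["rfs"]] + moved
      occ[k + 1L, ] <- cur
    }
    i <- k + 1L
    nxt <- c(
      pfs = cur[["pfs"]] * (1 - p$pfs_to_pd[i] - p$pfs_to_dead[i]),
      rfs = cur[["rfs"]] * (1 - p$rfs_to_pd - p$rfs_to_dead),
      pd = cur[["pd"]] * (1 - p$pd_to_dead[i]) +
        cur[["pfs"]] * p$pfs_to_pd[i] + cur[["rfs"]] * p$rfs_to_pd,
      dead = cur[["dead"]] + cur[["pfs"]] * p$pfs_to_dead[i] +
        cur[["rfs"]] * p$rfs_to_dead + cur[["pd"]] * p$pd_to_dead[i]
    )
    occ[k + 1L, ] <- cur
    occ[k + 2L, ] <- nxt
    cur <- nxt
    if (!is.null(stop_at_dead) && cur[["dead"]] >= stop_at_dead) {
      reached <- k + 1L
      break
    }
  }
  list(occupancy = occ[seq_len(reached + 1L), , drop = FALSE],
       moved = moved, cycles = reached)
}

#' Number of cycles to run
#'
#' Under `horizon_mode = "fixed_cycles"` this is simply
#' `settings$max_cycles` (the default, 139 cycles of 21 days, is about 8
#' years). Under `"mortality_fraction"` it is the smallest cycle count at
#' which the DEAD occupancy reaches `mortality_fraction_threshold` for the
#' slower-dying strategy; if either strategy fails to reach the threshold
#' within `max_cycles` an error reports the residual alive fraction.
#'
#' @param pars a `haic_params` bundle.
#' @return Integer number of cycles.
#' @export
determine_horizon <- function(pars) {
  s <- pars$settings
  if (s$horizon_mode == "fixed_cycles") return(as.integer(s$max_cycles))
  thr <- s$mortality_fraction_threshold
  if (thr == 0) return(0L)
  worst <- 0L
  for (id in names(pars$strategies)) {
    r <- cohort_recursion(pars, id, as.integer(s$max_cycles), stop_at_dead = thr)
    dead_end <- r$occupancy[nrow(r$occupancy), "dead"]
    if (dead_end < thr)
      abort_model(sprintf(
        "strategy '%s': %.2f%% still alive after max_cycles = %d; cannot reach %g%% mortality",
        id, 100 * (1 - dead_end), s$max_cycles, 100 * thr))
    worst <- max(worst, r$cycles)
  }
  as.integer(worst)
}

#' Run the Markov cohort
#'
#' Starts with the whole cohort progression-free, applies the cycle-specific
#' transition matrices of [build_transition_matrix()] and the one-off
#' hepatectomy branch, and returns the cycle-by-state occupancy trace up to
#' the horizon of [determine_horizon()].
#'
#' @inheritParams strategy_curves
#' @return An object of class `cohort_trace`: a list with the
#'   `(cycles+1) x 4` occupancy matrix (row k = start of cycle k, after the
#'   branch where applicable), `time_months`, the branch bookkeeping, and the
#'   strategy id. Rows sum to 1 and the DEAD column is non-decreasing.
#' @examples
#' tr <- run_cohort(default_parameters(), "sorafenib")
#' head(as.data.frame(tr))
#' @param validate revalidate the bundle first (set `FALSE` in tight loops
#'   that already validated it).
#' @export
run_cohort <- function(pars, strategy_id, validate = TRUE) {
  if (validate) validate_parameters(pars)
  n_cycles <- determine_horizon(pars)
  r <- cohort_recursion(pars, strategy_id, n_cycles)
  structure(
    list(occupancy = r$occupancy,
         time_months = (seq_len(nrow(r$occupancy)) - 1L) * cycle_length_months(pars),
         strategy_id = strategy_id,
         branch = list(cycle = pars$settings$hepatectomy_branch_cycle,
                       moved = r$moved),
         n_cycles = r$cycles),
    class = "cohort_trace"
  )
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = seq_len(nrow(x$occupancy)) - 1L,
             time_months = x$time_months,
             x$occupancy)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace, strategy '%s': %d cycles (%.1f years)\n",
              x$strategy_id, x$n_cycles, max(x$time_months) / 12))
  last <- x$occupancy[nrow(x$occupancy), ]
  cat(sprintf("  final occupancy: pfs %.4f rfs %.4f pd %.4f dead %.4f\n",
              last[1], last[2], last[3], last[4]))
  invisible(x)
}

#' Individual-level microsimulation of the same model
#'
#' Simulates `n_individuals` patients through the identical per-cycle
#' transition probabilities (and a Bernoulli hepatectomy branch) and returns
#' the mean occupancy trace. Serves as an independent stochastic cross-check
#' of [run_cohort()]: the mean trace converges to the cohort trace at rate
#' \eqn{1/\sqrt{n}}.
#'
#' @inheritParams strategy_curves
#' @param n_individuals number of simulated patients.
#' @param seed integer seed; identical seeds give identical output.
#' @return Matrix `(cycles+1) x 4` of mean occupancy.
#' @export
microsimulate <- function(pars, strategy_id, n_individuals, seed) {
  stopifnot(n_individuals >= 1)
  n_cycles <- determine_horizon(pars)
  p <- cycle_probs(pars, strategy_id, seq_len(n_cycles) - 1L)
  branch_cycle <- pars$settings$hepatectomy_branch_cycle
  frac <- pars$strategies[[strategy_id]]$hepatectomy_fraction
  set.seed(seed)
  state <- rep.int(1L, n_individuals) # 1 pfs, 2 rfs, 3 pd, 4 dead
  occ <- matrix(0, n_cycles + 1L, 4L, dimnames = list(NULL, STATES))
  tally <- function(s) tabulate(s, nbins = 4L) / n_individuals
  occ[1L, ] <- tally(state)
  for (k in seq_len(n_cycles) - 1L) {
    if (k == branch_cycle) {
      goes <- state == 1L & stats::runif(n_individuals) < frac
      state[goes] <- 2L
    }
    occ[k + 1L, ] <- tally(state) # start-of-cycle occupancy, post-branch
    i <- k + 1L
    r <- stats::runif(n_individuals)
    new <- state
    pfs <- state == 1L
    new[pfs & r < p$pfs_to_dead[i]] <- 4L
    new[pfs & r >= p$pfs_to_dead[i] &
          r < p$pfs_to_dead[i] + p$pfs_to_pd[i]] <- 3L
    rfs <- state == 2L
    new[rfs & r < p$rfs_to_dead] <- 4L
    new[rfs & r >= p$rfs_to_dead & r < p$rfs_to_dead + p$rfs_to_pd] <- 3L
    pd <- state == 3L
    new[pd & r < p$pd_to_dead[i]] <- 4L
    state <- new
  }
  occ[n_cycles + 1L, ] <- tally(state)
  occ
}
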