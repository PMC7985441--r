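# Synthetic-data generators. The published analysis rests on Kaplan-Meier
# curves digitized from the source trial's figures; those coordinates were
# never deposited, so the package generates stand-ins from known Weibull
# truths (with digitization-style jitter) and every downstream stage is
# exercised against them.

#' Generate synthetic digitized survival-curve points
#'
#' Evenly spaced time points in `(0, max_time]` with survival `S(t)` plus
#' optional Gaussian noise on the survival scale (mimicking digitization
#' jitter), clamped to `(0, 1]` and forced non-increasing by a running
#' minimum -- so the output always satisfies the digitized-curve invariants
#' the fitter expects.
#'
#' @param truth a [weibull_params()] object, the generating curve.
#' @param n_points number of points (>= 3).
#' @param max_time largest time in months.
#' @param noise_sd standard deviation of the survival-scale noise (>= 0).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return Data frame with columns `time_months`, `survival`.
#' @export
generate_curve_points <- function(truth, n_points, max_time, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(n_points >= 3, max_time > 0, noise_sd >= 0)
  truth <- as_weibull_params(truth)
  t <- seq(max_time / n_points, max_time, length.out = n_points)
  s <- survival_at(truth, t)
  if (noise_sd > 0) {
    set.seed(seed)
    s <- s + stats::rnorm(n_points, 0, noise_sd)
  }
  s <- pmin(pmax(s, 1e-12), 1)
  s <- cummin(s)
  data.frame(time_months = t, survival = s)
}

#' Minimal background-mortality table
#'
#' A flat annual all-cause death probability, the form the model consumes
#' (an age schedule can be emulated by rebuilding the bundle per age band).
#'
#' @param flat_annual_q annual death probability in \[0, 1).
#' @return List with element `flat_annual_probability`.
#' @export
generate_mortality_fixture <- function(flat_annual_q) {
  check_number(flat_annual_q, "flat_annual_q", 0, 1 - 1e-12)
  list(flat_annual_probability = flat_annual_q)
}

#' Random valid parameter bundle for property tests
#'
#' Draws a bundle satisfying every structural invariant -- positive Weibull
#' parameters, costs >= 0, utilities and probabilities in \[0, 1\], the
#' subsequent-treatment mix summing to 1 -- with ranges rebuilt around the
#' drawn bases. OS-median calibration is switched off (a random curve has no
#' trial median to calibrate to) and the horizon kept short so fuzzing stays
#' cheap. Deterministic under a fixed seed.
#'
#' @param seed integer seed.
#' @return A validated `haic_params` bundle.
#' @export
random_valid_bundle <- function(seed) {
  set.seed(seed)
  pars <- default_parameters()
  pars$settings$os_median_calibration <- "none"
  pars$settings$max_cycles <- 80L
  pars$settings$discount_rate_annual <- stats::runif(1, 0, 0.05)
  pars$settings$pfs_death_rule <- sample(c("os_competing", "os_excess", "background"), 1)
  pars$settings$pd_cost_mode <- sample(c("bsc", "mix"), 1)
  pars$settings$half_cycle_correction <- sample(c(TRUE, FALSE), 1)
  pars$mortality$flat_annual_probability <- stats::runif(1, 0, 0.05)
  pars$recurrence$cumulative_incidence <- stats::runif(1, 0.02, 0.7)
  pars$utilities$pfs <- stats::runif(1, 0.4, 0.95)
  pars$utilities$pd <- stats::runif(1, 0.2, pars$utilities$pfs)
  for (s in SAE_TYPES)
    pars$utilities$disutility[[s]] <- stats::runif(1, 0, 0.1)
  for (nm in names(pars$costs$per_cycle))
    pars$costs$per_cycle[[nm]] <- pars$costs$per_cycle[[nm]] * stats::runif(1, 0.5, 1.5)
  for (nm in names(pars$costs$one_time))
    pars$costs$one_time[[nm]] <- pars$costs$one_time[[nm]] * stats::runif(1, 0.5, 1.5)
  pars$costs$bsa_patient <- stats::runif(1, 1.3, 2.1)
  for (arm in c("sorahaic", "sorafenib")) {
    st <- pars$strategies[[arm]]
    st$pfs_weibull <- list(scale = stats::runif(1, 0.02, 0.4),
                           shape = stats::runif(1, 0.6, 2))
    st$os_weibull <- list(scale = stats::runif(1, 0.01, 0.2),
                          shape = stats::runif(1, 0.6, 2))
    st$hepatectomy_fraction <- stats::runif(1, 0, 0.3)
    for (s in SAE_TYPES) st$sae_incidence[[s]] <- stats::runif(1, 0, 0.5)
    m <- stats::rgamma(3, 1)
    m <- m / sum(m)
    st$subsequent_mix <- list(sorafenib = m[1], haic = m[2], bsc = m[3])
    pars$strategies[[arm]] <- st
  }
  # rebuild ranges so base values sit inside them
  specs <- param_registry()
  pars$ranges <- stats::setNames(lapply(seq_len(nrow(specs)), function(i) {
    base <- pluck_path(pars, specs$path[[i]])
    r <- list(min = base * 0.8, max = base * 1.2,
              dist = switch(specs$group[i], cost = "gamma",
                            utility = , proportion = "beta", "normal"))
    if (specs$param_id[i] == "discount_rate") {
      r <- list(min = 0, max = 0.05, dist = "fixed")
    } else if (r$dist == "beta") {
      r$min <- max(r$min, 0); r$max <- min(r$max, 1)
    }
    r
  }), specs$param_id)
  validate_parameters(pars)
  pars
}
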