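# Deterministic (tornado) and probabilistic sensitivity analysis.

# run both strategies through the full pipeline and return deltas + ICER
run_pair <- function(pars, validate = TRUE) {
  if (validate) validate_parameters(pars)
  a <- accrue(run_cohort(pars, "sorahaic", validate = FALSE), pars)
  b <- accrue(run_cohort(pars, "sorafenib", validate = FALSE), pars)
  compute_cea(a, b)
}

#' Base-case cost-effectiveness analysis
#'
#' Runs both strategies through the cohort engine and valuation and returns
#' the incremental results (combination arm vs sorafenib alone).
#'
#' @param pars a `haic_params` bundle, e.g. [default_parameters()].
#' @return A [compute_cea()] object.
#' @examples
#' base_case(default_parameters())
#' @export
base_case <- function(pars) run_pair(pars, validate = TRUE)

#' One-way deterministic sweep of a single parameter
#'
#' Re-runs the full two-strategy pipeline twice, once with the parameter at
#' each bound and everything else at base, and records the ICER per QALY at
#' both ends. Bounds default to the configured range (published bounds where
#' available, otherwise base +/- 20%; the discount rate sweeps 0-5% and the
#' recurrence rate its 3-/7-year bounds).
#'
#' @param pars a `haic_params` bundle.
#' @param param_id a parameter id from [param_registry()].
#' @param low,high sweep bounds; `NULL` uses the configured range.
#' @return One-row data frame: `param_id`, `base`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `span`.
#' @export
one_way_sweep <- function(pars, param_id, low = NULL, high = NULL) {
  specs <- psa_specs(pars)
  i <- match(param_id, specs$param_id)
  if (is.na(i)) abort_validation("unknown parameter id", param_id)
  low <- low %||% specs$min[i]
  high <- high %||% specs$max[i]
  if (low > high) abort_validation("low > high", param_id)
  icer_at <- function(v) {
    res <- run_pair(set_parameter_value(pars, param_id, v), validate = FALSE)
    if (res$icer_per_qaly_flag == "ok") res$icer_per_qaly else NA_real_
  }
  il <- icer_at(low)
  ih <- icer_at(high)
  data.frame(param_id = param_id, base = specs$base[i], low = low, high = high,
             icer_at_low = il, icer_at_high = ih, span = abs(ih - il),
             stringsAsFactors = FALSE)
}

#' Tornado table: one-way sweeps of every ranged parameter
#'
#' @param pars a `haic_params` bundle.
#' @return Data frame of [one_way_sweep()] rows, sorted by decreasing span,
#'   of class `haic_tornado` (also carries the base-case ICER as attribute
#'   `icer_base`).
#' @examples
#' \donttest{
#' tor <- tornado(default_parameters())
#' head(tor, 3)
#' }
#' @export
tornado <- function(pars) {
  validate_parameters(pars)
  specs <- psa_specs(pars)
  rows <- lapply(specs$param_id, function(id) one_way_sweep(pars, id))
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  base <- run_pair(pars, validate = FALSE)
  structure(out, class = c("haic_tornado", "data.frame"),
            icer_base = base$icer_per_qaly)
}

# method-of-moments beta/gamma; range read as a 95% interval
draw_parameter <- function(dist, base, min, max) {
  sd <- (max - min) / 3.92
  if (sd <= 0 || dist == "fixed") return(base)
  switch(dist,
    beta = {
      if (base <= 0 || base >= 1) return(base)
      nu <- base * (1 - base) / sd^2 - 1
      if (nu <= 0) {
        warning(sprintf("beta moments infeasible at sd=(max-min)/3.92; using (max-min)/6 (base %g)", base))
        sd <- (max - min) / 6
        nu <- base * (1 - base) / sd^2 - 1
        if (nu <= 0) return(base)
      }
      stats::rbeta(1, base * nu, (1 - base) * nu)
    },
    gamma = {
      if (base <= 0) return(base)
      shape <- (base / sd)^2
      stats::rgamma(1, shape = shape, rate = shape / base)
    },
    normal = max(stats::rnorm(1, base, sd), 1e-6),
    base)
}

#' Draw one probabilistic-sensitivity-analysis parameter bundle
#'
#' Utilities, probabilities and proportions are drawn from beta
#' distributions, costs from gamma and BSA from normal, each matched by
#' method of moments to mean = base value and SD = (max - min)/3.92 (the
#' range read as a 95% interval). Parameters marked `fixed` (the discount
#' rate) are untouched. The three subsequent-treatment-mix components are
#' drawn independently and renormalised to sum to 1. If beta moments are
#' infeasible for the given range the SD falls back to (max - min)/6 with a
#' warning.
#'
#' @param pars a `haic_params` bundle (the PSA specification comes from
#'   [psa_specs()]).
#' @param seed integer seed; the same seed reproduces the same bundle.
#' @return The sampled bundle; attribute `"sampled"` carries the drawn
#'   values as a named vector.
#' @export
sample_parameters <- function(pars, seed) {
  specs <- psa_specs(pars)
  set.seed(seed)
  vals <- stats::setNames(numeric(nrow(specs)), specs$param_id)
  for (i in seq_len(nrow(specs)))
    vals[i] <- draw_parameter(specs$dist[i], specs$base[i],
                              specs$min[i], specs$max[i])
  out <- pars
  mix_ids <- grep("^mix_", specs$param_id, value = TRUE)
  for (id in setdiff(specs$param_id, c(mix_ids, "discount_rate")))
    out <- poke_path(out, param_registry()$path[[match(id, param_registry()$param_id)]],
                     unname(vals[id]))
  for (arm in c("sorahaic", "sorafenib")) {
    ids <- paste0("mix_", arm, "_", c("sorafenib", "haic", "bsc"))
    v <- vals[ids]
    v <- v / sum(v)
    vals[ids] <- v
    out$strategies[[arm]]$subsequent_mix <-
      list(sorafenib = unname(v[1L]), haic = unname(v[2L]), bsc = unname(v[3L]))
  }
  attr(out, "sampled") <- vals
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo repetitions (10,000 in the reference analysis) in which every
#' uncertain parameter is redrawn via [sample_parameters()] and the full
#' two-strategy pipeline is rerun, recording the incremental cost and QALY
#' pair of each draw. Draw `i` uses seed `seed + i`, so extending the number
#' of draws never changes earlier draws. Failing draws are skipped and
#' counted in the attribute `n_failed`.
#'
#' @param pars a `haic_params` bundle.
#' @param n_draws number of Monte-Carlo repetitions (>= 1).
#' @param seed integer root seed (defaults to `settings$random_seed`).
#' @return Data frame of class `haic_psa` with columns `draw`, `delta_cost`,
#'   `delta_qalys` and one column per sampled parameter.
#' @export
run_psa <- function(pars, n_draws = 10000, seed = NULL) {
  validate_parameters(pars)
  stopifnot(n_draws >= 1)
  seed <- as.integer(seed %||% pars$settings$random_seed)
  specs <- psa_specs(pars)
  sampled <- matrix(NA_real_, n_draws, nrow(specs),
                    dimnames = list(NULL, specs$param_id))
  dc <- dq <- rep(NA_real_, n_draws)
  n_failed <- 0L
  for (i in seq_len(n_draws)) {
    res <- tryCatch({
      pi <- sample_parameters(pars, seed + i)
      sampled[i, ] <- attr(pi, "sampled")
      run_pair(pi, validate = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    dc[i] <- res$delta_cost
    dq[i] <- res$delta_qalys
  }
  if (n_failed > 0L)
    warning(sprintf("%d of %d PSA draws failed and were skipped", n_failed, n_draws))
  ok <- !is.na(dc)
  out <- data.frame(draw = seq_len(n_draws)[ok], delta_cost = dc[ok],
                    delta_qalys = dq[ok], sampled[ok, , drop = FALSE],
                    row.names = NULL)
  structure(out, class = c("haic_psa", "data.frame"),
            n_failed = n_failed, seed = seed)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param samples a [run_psa()] result (needs `delta_cost`, `delta_qalys`).
#' @param wtp_grid numeric vector of thresholds in USD per QALY.
#' @return Data frame with columns `wtp` and `acceptability`.
#' @export
ceac <- function(samples, wtp_grid) {
  if (NROW(samples) == 0L) abort_model("ceac: no PSA samples")
  data.frame(
    wtp = wtp_grid,
    acceptability = vapply(wtp_grid, function(w)
      mean(nmb(samples$delta_cost, samples$delta_qalys, w) > 0), 0)
  )
}
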