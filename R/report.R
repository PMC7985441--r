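# High-level runs that tie the stages together and write the tabular
# artifacts (CSV/JSON). These functions are what the command-line wrapper
# in inst/cli/ calls; plots are optional conveniences layered on top.

default_wtp_grid <- function(pars) {
  sort(unique(c(seq(0, 100000, by = 1000),
                unlist(pars$settings$wtp_thresholds))))
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the base case and write its artifacts
#'
#' Runs both strategies, and (when `out_dir` is given) writes the per-cycle
#' traces (`trace_<strategy>.csv`), a results table mirroring the summary
#' layout of the reference analysis (`base_case_results.csv`), the
#' willingness-to-pay decisions (`decisions.csv`) and a JSON run report.
#'
#' @param pars a `haic_params` bundle.
#' @param out_dir output directory (created if missing); `NULL` writes
#'   nothing.
#' @return Invisibly, a list: `cea`, `decisions`, `accruals`, `traces`,
#'   `horizon_cycles`, `files` (paths written).
#' @examples
#' res <- run_base_case(default_parameters())
#' res$cea
#' @export
run_base_case <- function(pars, out_dir = NULL) {
  validate_parameters(pars)
  traces <- lapply(stats::setNames(nm = names(pars$strategies)),
                   function(id) run_cohort(pars, id, validate = FALSE))
  accruals <- lapply(traces, accrue, pars = pars)
  cea <- compute_cea(accruals$sorahaic, accruals$sorafenib)
  decisions <- decide(cea, pars$settings$wtp_thresholds)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(traces))
      files <- c(files, write_csv_plain(
        as.data.frame(traces[[id]]), file.path(out_dir, sprintf("trace_%s.csv", id))))
    tab <- cea$strategies
    tab$icer_per_ly <- c(cea$icer_per_ly, NA)
    tab$icer_per_qaly <- c(cea$icer_per_qaly, NA)
    files <- c(files,
               write_csv_plain(tab, file.path(out_dir, "base_case_results.csv")),
               write_csv_plain(decisions, file.path(out_dir, "decisions.csv")))
    report <- list(
      horizon_cycles = traces$sorahaic$n_cycles,
      settings = pars$settings,
      results = list(
        strategies = cea$strategies,
        delta_cost = cea$delta_cost, delta_lys = cea$delta_lys,
        delta_qalys = cea$delta_qalys,
        icer_per_qaly = cea$icer_per_qaly, icer_per_ly = cea$icer_per_ly),
      decisions = decisions,
      files = files)
    rp <- file.path(out_dir, "run_report.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, rp)
  }
  invisible(list(cea = cea, decisions = decisions, accruals = accruals,
                 traces = traces, horizon_cycles = traces$sorahaic$n_cycles,
                 files = files))
}

#' Run the one-way sensitivity analysis and write the tornado table
#'
#' @param pars a `haic_params` bundle.
#' @param out_dir output directory; `NULL` writes nothing.
#' @param plot also write `tornado.png` (needs ggplot2).
#' @return Invisibly, a list: `tornado` (sorted table), `files`.
#' @export
run_owsa <- function(pars, out_dir = NULL, plot = FALSE) {
  tor <- tornado(pars)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_csv_plain(as.data.frame(tor), file.path(out_dir, "tornado.csv"))
    if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
      f <- file.path(out_dir, "tornado.png")
      ok <- tryCatch({
        ggplot2::ggsave(f, plot_tornado(tor), width = 8, height = 7, dpi = 150)
        TRUE
      }, error = function(e) FALSE)
      if (ok) files <- c(files, f)
    }
  }
  invisible(list(tornado = tor, files = files))
}

#' Run the probabilistic sensitivity analysis and write its artifacts
#'
#' Writes the per-draw samples with acceptance indicators at each configured
#' threshold (`psa_samples.csv`), the cost-effectiveness acceptability curve
#' over a 0-100k grid plus the named thresholds (`ceac.csv`), and optional
#' CE-plane / CEAC plots.
#'
#' @param pars a `haic_params` bundle.
#' @param n_draws Monte-Carlo repetitions (reference analysis: 10,000).
#' @param seed root seed (defaults to `settings$random_seed`).
#' @param out_dir output directory; `NULL` writes nothing.
#' @param plot also write plot files (needs ggplot2).
#' @return Invisibly, a list: `psa`, `ceac`, `acceptability` (at the named
#'   thresholds), `files`.
#' @export
run_psa_report <- function(pars, n_draws = 10000, seed = NULL, out_dir = NULL,
                           plot = FALSE) {
  samples <- run_psa(pars, n_draws = n_draws, seed = seed)
  grid <- default_wtp_grid(pars)
  curve <- ceac(samples, grid)
  thresholds <- unlist(pars$settings$wtp_thresholds)
  acc <- stats::setNames(
    curve$acceptability[match(thresholds, curve$wtp)], names(thresholds))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- as.data.frame(samples)
    for (nm in names(thresholds))
      out[[paste0("accept_at_", nm)]] <-
        nmb(samples$delta_cost, samples$delta_qalys, thresholds[[nm]]) > 0
    files <- c(write_csv_plain(out, file.path(out_dir, "psa_samples.csv")),
               write_csv_plain(curve, file.path(out_dir, "ceac.csv")))
    if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
      for (nm in c("ceac", "ce_plane")) {
        f <- file.path(out_dir, paste0(nm, ".png"))
        p <- if (nm == "ceac") plot_ceac(curve, thresholds)
             else plot_ce_plane(samples, thresholds)
        ok <- tryCatch({
          ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 150)
          TRUE
        }, error = function(e) FALSE)
        if (ok) files <- c(files, f)
      }
    }
  }
  invisible(list(psa = samples, ceac = curve, acceptability = acc, files = files))
}
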