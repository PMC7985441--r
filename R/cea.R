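# Incremental cost-effectiveness results and willingness-to-pay decisions.

#' Incremental cost-effectiveness of one strategy against another
#'
#' Computes the cost, life-year and QALY deltas and the incremental
#' cost-effectiveness ratios (per QALY and per LY) of `intervention` versus
#' `comparator`. Dominance is flagged instead of reporting a meaningless
#' negative ratio: `"dominant"` when the intervention is cheaper and more
#' effective, `"dominated"` when costlier and less effective, and the ICER
#' is `NA` with flag `"undefined"` when the effect delta is zero.
#'
#' @param intervention,comparator [accrue()] results from the same bundle.
#' @return An object of class `haic_cea` with per-strategy totals, deltas,
#'   `icer_per_qaly`, `icer_per_ly` and dominance flags.
#' @export
compute_cea <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "haic_accrual"), inherits(comparator, "haic_accrual"))
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  dl <- intervention$total_lys - comparator$total_lys
  ratio <- function(dcost, deff) {
    if (deff == 0) return(list(icer = NA_real_, flag = "undefined"))
    if (deff > 0 && dcost <= 0) return(list(icer = NA_real_, flag = "dominant"))
    if (deff < 0 && dcost >= 0) return(list(icer = NA_real_, flag = "dominated"))
    list(icer = dcost / deff, flag = "ok")
  }
  rq <- ratio(dc, dq)
  rl <- ratio(dc, dl)
  structure(
    list(strategies = data.frame(
           strategy = c(intervention$name, comparator$name),
           cost = c(intervention$total_cost, comparator$total_cost),
           lys = c(intervention$total_lys, comparator$total_lys),
           qalys = c(intervention$total_qalys, comparator$total_qalys),
           stringsAsFactors = FALSE),
         delta_cost = dc, delta_qalys = dq, delta_lys = dl,
         icer_per_qaly = rq$icer, icer_per_qaly_flag = rq$flag,
         icer_per_ly = rl$icer, icer_per_ly_flag = rl$flag),
    class = "haic_cea"
  )
}

#' @export
print.haic_cea <- function(x, ...) {
  cat("Cost-effectiveness summary (discounted)\n")
  df <- x$strategies
  df$cost <- sprintf("%.2f", df$cost)
  df$lys <- sprintf("%.4f", df$lys)
  df$qalys <- sprintf("%.4f", df$qalys)
  print(df, row.names = FALSE)
  cat(sprintf("  incremental: cost $%.2f | %.4f LYs | %.4f QALYs\n",
              x$delta_cost, x$delta_lys, x$delta_qalys))
  icer_str <- function(icer, flag)
    if (flag == "ok") sprintf("$%.2f", icer) else flag
  cat(sprintf("  ICER: %s per QALY, %s per LY\n",
              icer_str(x$icer_per_qaly, x$icer_per_qaly_flag),
              icer_str(x$icer_per_ly, x$icer_per_ly_flag)))
  invisible(x)
}

#' Net monetary benefit
#'
#' \eqn{\mathrm{NMB} = \lambda \Delta E - \Delta C} at willingness-to-pay
#' \eqn{\lambda}; positive NMB means the intervention is cost-effective at
#' that threshold.
#'
#' @param delta_cost incremental cost in USD (vectorised).
#' @param delta_effect incremental effectiveness in QALYs (vectorised).
#' @param wtp willingness-to-pay threshold in USD per QALY (>= 0).
#' @return NMB in USD.
#' @export
nmb <- function(delta_cost, delta_effect, wtp) {
  if (any(wtp < 0)) abort_model("willingness-to-pay must be non-negative")
  wtp * delta_effect - delta_cost
}

#' Cost-effectiveness decisions at configured thresholds
#'
#' One decision per willingness-to-pay threshold, with the net monetary
#' benefit and whether the intervention is cost-effective there (positive
#' NMB; a dominant intervention is cost-effective at every threshold, a
#' dominated one at none).
#'
#' @param result a [compute_cea()] object.
#' @param thresholds named list or vector of USD-per-QALY thresholds.
#' @return Data frame with columns `label`, `wtp`, `nmb`, `cost_effective`.
#' @export
decide <- function(result, thresholds) {
  stopifnot(inherits(result, "haic_cea"))
  wtp <- unlist(thresholds)
  labels <- names(wtp) %||% as.character(wtp)
  b <- nmb(result$delta_cost, result$delta_qalys, wtp)
  data.frame(label = labels, wtp = unname(wtp), nmb = unname(b),
             cost_effective = unname(b > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
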