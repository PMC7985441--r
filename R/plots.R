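# ggplot2 figures mirroring the usual CEA graphics: tornado diagram,
# acceptability curve, and incremental cost-effectiveness plane.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting; install it or use the CSV outputs")
}

#' Tornado diagram
#'
#' Horizontal bars from the ICER at each parameter's lower to upper bound,
#' widest span on top, with the base-case ICER as a vertical reference.
#'
#' @param tor a [tornado()] table.
#' @param top number of parameters to display.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tor, top = 15) {
  need_ggplot2()
  df <- utils::head(as.data.frame(tor), top)
  df <- df[!is.na(df$span), , drop = FALSE]
  df$param_id <- factor(df$param_id, levels = rev(df$param_id))
  df$lo <- pmin(df$icer_at_low, df$icer_at_high)
  df$hi <- pmax(df$icer_at_low, df$icer_at_high)
  ggplot2::ggplot(df, ggplot2::aes(y = param_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       yend = param_id),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tor, "icer_base"), linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param curve a [ceac()] data frame.
#' @param thresholds optional named vector of WTP thresholds to mark.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, thresholds = NULL) {
  need_ggplot2()
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = wtp, y = acceptability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds))
    p <- p + ggplot2::geom_vline(xintercept = unname(unlist(thresholds)),
                                 linetype = 3)
  p
}

#' Incremental cost-effectiveness plane
#'
#' PSA draws as (incremental QALYs, incremental cost) points, with lines of
#' slope equal to each willingness-to-pay threshold through the origin.
#'
#' @param samples a [run_psa()] result.
#' @param thresholds optional named vector of WTP thresholds.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(samples, thresholds = NULL) {
  need_ggplot2()
  df <- as.data.frame(samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = delta_qalys, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds))
    for (w in unlist(thresholds))
      p <- p + ggplot2::geom_abline(slope = w, intercept = 0, linetype = 3)
  p
}

utils::globalVariables(c("param_id", "lo", "hi", "wtp", "acceptability",
                         "delta_qalys", "delta_cost"))
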