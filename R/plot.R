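#' Plot ensemble metric trajectories
#'
#' Base-graphics line plot of the ensemble mean of a metric over time, with
#' the bootstrap bands when present. Intended as a quick diagnostic, not a
#' publication figure.
#'
#' @param x an `ensemble_summary`.
#' @param metric metric name (default `"prevalence"`).
#' @param ... passed to [graphics::plot()].
#' @return The summary, invisibly.
#' @export
plot.ensemble_summary <- function(x, metric = "prevalence", ...) {
  s <- x$summary[x$summary$metric == metric, ]
  graphics::plot(s$step, s$mean, type = "l", xlab = "time step",
                 ylab = metric, ...)
  if ("lower_95" %in% names(s)) {
    graphics::lines(s$step, s$lower_95, lty = 2, col = "grey40")
    graphics::lines(s$step, s$upper_95, lty = 2, col = "grey40")
  }
  if ("lower_99" %in% names(s)) {
    graphics::lines(s$step, s$lower_99, lty = 3, col = "grey70")
    graphics::lines(s$step, s$upper_99, lty = 3, col = "grey70")
  }
  graphics::abline(v = x$baseline_step, col = "grey80")
  invisible(x)
}
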