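# ggplot2-based diagnostics; ggplot2 is suggested, not imported.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
}

#' Plot a visual predictive check
#'
#' Observed 10/50/90th percentile lines per bin over the simulated 95%
#' confidence ribbons.
#'
#' @param x A `vpc_result` from [vpc_pvc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.vpc_result <- function(x, ...) {
  need_ggplot()
  b <- x$bins
  ggplot2::ggplot(b, ggplot2::aes(x = time_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p10_lo,
                                      ymax = sim_p10_hi),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p50_lo,
                                      ymax = sim_p50_hi),
                         alpha = 0.3, fill = "firebrick") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p90_lo,
                                      ymax = sim_p90_hi),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = obs_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p10), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p90), linetype = 2) +
    ggplot2::labs(x = "time after dose (h)",
                  y = if (x$corrected) "prediction-corrected concentration (mg/L)"
                      else "concentration (mg/L)")
}

#' Plot PTA-versus-MIC step curves
#'
#' One panel per renal band, one curve per regimen, with the 90% adequacy
#' line.
#'
#' @param x A `pta_grid` from [pta_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.pta_grid <- function(x, ...) {
  need_ggplot()
  d <- as.data.frame(x)
  d$regimen <- sprintf("%g mg q%gh (%gh inf)", d$dose, d$interval, d$tinf)
  ggplot2::ggplot(d, ggplot2::aes(x = mic, y = pta,
                                  colour = regimen)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 90, linetype = 3) +
    ggplot2::scale_x_log10(breaks = unique(d$mic)) +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "MIC (mg/L)", y = "PTA (%)",
                  title = unique(d$target))
}

utils::globalVariables(c("time_mid", "sim_p10_lo", "sim_p10_hi", "sim_p50_lo",
                         "sim_p50_hi", "sim_p90_lo", "sim_p90_hi", "obs_p10",
                         "obs_p50", "obs_p90", "mic", "pta", "regimen"))
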