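#' Plot a metric surface over the stimulus grid
#'
#' Filled-contour view of one metric from a [run_sweep()] table as a
#' function of mean excitatory conductance (x) and contrast (y) for one
#' regime, the standard way these results are displayed.
#'
#' @param metrics Data frame from [run_sweep()].
#' @param metric Column name to plot (e.g. `"rate"`, `"mi_rate"`,
#'   `"bits_per_spike"`, `"atp_per_second"`, `"bits_per_atp"`).
#' @param inhibition_ratio Regime to show.
#' @param ... Passed to [graphics::filled.contour()].
#' @return Invisibly, the plotted value matrix (mu_e x contrast).
#' @export
plot_metric_surface <- function(metrics, metric = "rate",
                                inhibition_ratio = 0, ...) {
  m <- metrics[metrics$inhibition_ratio == inhibition_ratio, ]
  if (nrow(m) == 0) stop("no rows for this inhibition ratio")
  if (!metric %in% names(m)) stop("unknown metric: ", metric)
  mu <- sort(unique(m$mu_e))
  ct <- sort(unique(m$contrast))
  z <- matrix(NA_real_, length(mu), length(ct))
  z[cbind(match(m$mu_e, mu), match(m$contrast, ct))] <- m[[metric]]
  graphics::filled.contour(
    mu, ct, z,
    xlab = "mean excitatory conductance (uS/cm^2)",
    ylab = "contrast (sd/mean)",
    main = sprintf("%s (inhibition ratio %g)", metric, inhibition_ratio),
    ...)
  invisible(z)
}
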