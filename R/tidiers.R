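#' Tidy a fitted stomatal model
#'
#' One row per free parameter with posterior mean, SD, central 95%
#' credible interval and split-half R-hat.
#'
#' @param x a `stomatal_fit`.
#' @param ... unused.
#' @return tibble: `term, estimate, std.error, conf.low, conf.high, rhat`.
#' @method tidy stomatal_fit
#' @export
tidy.stomatal_fit <- function(x, ...) {
  q <- apply(x$draws, 2, stats::quantile, probs = c(0.025, 0.975))
  tibble::tibble(
    term = x$par_names,
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, stats::sd),
    conf.low = q[1, ], conf.high = q[2, ],
    rhat = unname(x$rhat)
  )
}

#' One-row summary of a fitted stomatal model
#'
#' @param x a `stomatal_fit`.
#' @param ... unused.
#' @return tibble: `level, n_records, n_free_parameters, deviance`
#'   (posterior mean deviance, the quantity WinBUGS-style summaries print),
#'   `deviance_at_mean` (plug-in at the posterior means), `dic,
#'   residual_sd, max_rhat`.
#' @method glance stomatal_fit
#' @export
glance.stomatal_fit <- function(x, ...) {
  d <- dic(x$deviance_trace, x$deviance_at_mean)
  tibble::tibble(
    level = x$level, n_records = x$n_records,
    n_free_parameters = x$n_free_parameters,
    deviance = d$mean_deviance, deviance_at_mean = x$deviance_at_mean,
    dic = d$dic,
    residual_sd = x$residual_sd,
    max_rhat = max(x$rhat, na.rm = TRUE)
  )
}

#' @export
print.stomatal_fit <- function(x, ...) {
  cat("Stomatal model fit (", x$level, " level)\n", sep = "")
  cat("  records:", x$n_records, " units:", length(x$units),
      " free parameters:", x$n_free_parameters, "\n")
  cat("  deviance (posterior-mean plug-in):",
      format(x$deviance_at_mean, digits = 5), "\n")
  cat("  residual SD:", format(x$residual_sd, digits = 4),
      " mol m-2 s-1\n")
  cat("  max split R-hat:", format(max(x$rhat, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Contour plot of a response surface
#'
#' @param object a `behavior_grid` from [response_surface()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot behavior_grid
#' @export
autoplot.behavior_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$psi_soil, y = .data$d,
                                       z = .data$g_s)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::labs(
      x = "Soil water potential (MPa)",
      y = "Scaled vapor pressure deficit (-)",
      fill = expression(g[s] ~ "(mol" ~ m^-2 ~ s^-1 * ")"),
      title = attr(object, "params_label")
    )
}

#' Plot ensemble mean +/- SD conductance curves
#'
#' @param curves output of [ensemble_curves()].
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plot_ensemble_curves <- function(curves, xlab = "Soil water potential (MPa)") {
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$mean))
  grp <- setdiff(names(curves), c("x", "mean", "sd", "n"))
  if (length(grp) == 1) {
    p <- p + ggplot2::aes(colour = .data[[grp]], fill = .data[[grp]])
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = expression(g[s] ~ "(mol" ~ m^-2 ~ s^-1 * ")"))
}

#' Trace plot of the posterior deviance
#'
#' @param fit a `stomatal_fit`.
#' @return a ggplot object.
#' @export
plot_deviance_trace <- function(fit) {
  df <- tibble::tibble(iteration = seq_along(fit$deviance_trace),
                       deviance = fit$deviance_trace,
                       chain = factor(fit$chain))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$deviance,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Kept iteration", y = "Deviance")
}
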