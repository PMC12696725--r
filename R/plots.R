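#' Plot a respirometry trace with its baseline fit
#'
#' @param object A `resp_session`.
#' @param baseline Optional `resp_baseline` to overlay.
#' @param window Optional integration window `c(t0, t1)` to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resp_session
#' @export
autoplot.resp_session <- function(object, baseline = NULL, window = NULL, ...) {
  p <- ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$time_s, y = .data$co2_ppm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$injection_time_s,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = expression(CO[2] ~ "(ppm)"),
                  title = object$session_id,
                  subtitle = if (object$is_control) "control syringe" else
                    paste("animal", object$individual_id)) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue")
  }
  if (!is.null(baseline)) {
    bl <- tibble::tibble(time_s = object$trace$time_s,
                         co2_ppm = predict(baseline, object$trace$time_s))
    p <- p + ggplot2::geom_line(data = bl, colour = "firebrick", linetype = "dotted")
  }
  p
}

#' Plot the mass-scaling relation on log-log axes
#'
#' Points are the observed (mass, rate) pairs; lines are the fitted
#' common-slope allometry per host.
#'
#' @param object An `allometry_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allometry_fit
#' @export
autoplot.allometry_fit <- function(object, ...) {
  d <- object$data
  grid <- tidyr::expand_grid(
    host = factor(levels(d$host), levels = levels(d$host)),
    ln_mass = seq(min(d$ln_mass), max(d$ln_mass), length.out = 50)
  )
  grid$ln_rate <- log(object$coefficient_a[as.character(grid$host)]) +
    object$exponent_b * grid$ln_mass
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ln_mass, y = .data$ln_rate,
                                  colour = .data$host)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "ln mass (g)", y = expression("ln " * dot(V) * CO[2] ~ "(mL " * h^-1 * ")"),
                  colour = "host plant") +
    ggplot2::theme_minimal()
}

#' Residual quantile-quantile plot for a mixed-model fit
#'
#' @param object An `lmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lmm_fit
#' @export
autoplot.lmm_fit <- function(object, ...) {
  d <- tibble::tibble(resid = residuals(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(sample = .data$resid)) +
    ggplot2::stat_qq(size = 0.8, alpha = 0.6) +
    ggplot2::stat_qq_line(colour = "firebrick") +
    ggplot2::labs(x = "theoretical quantiles", y = "residuals",
                  title = deparse(object$formula)) +
    ggplot2::theme_minimal()
}
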