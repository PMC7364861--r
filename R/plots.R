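#' Plot a trajectory
#'
#' Hormones and gland masses against time, one facet per variable.
#'
#' @param object An `hpa_trajectory`.
#' @param variables Subset of state variables to show (default: all but
#'   the exogenous-CRH tracer unless it is nonzero).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hpa_trajectory <- function(object, variables = NULL, ...) {
  long <- tidy(object)
  if (is.null(variables)) {
    variables <- setdiff(unique(long$variable), "x1E")
    if (any(object$data$x1E > 0)) variables <- c(variables, "x1E")
  }
  long <- long[long$variable %in% variables, ]
  long$variable <- factor(long$variable, levels = variables)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted", colour = "grey50") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "level (baseline = 1)",
                  title = paste("HPA trajectory:", object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot a CRH-test response timeline
#'
#' ACTH and cortisol peak-response ratios against test day, with the
#' normality band and stress end marked. Ratios below 1 are blunted
#' responses.
#'
#' @param object An `hpa_timeline`.
#' @param normal_band Band half-width to shade (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hpa_timeline <- function(object, normal_band = 0.05, ...) {
  long <- tidy(object)
  stress_end <- attr(object, "stress_end")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$ratio,
                                          colour = .data$hormone)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 1 - normal_band, ymax = 1 + normal_band,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "test day", y = "peak response ratio (case / control)",
                  colour = NULL,
                  title = paste("CRH-test responses:", attr(object, "variant"))) +
    ggplot2::theme_minimal()
  if (is.finite(stress_end)) {
    p <- p + ggplot2::geom_vline(xintercept = stress_end,
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
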