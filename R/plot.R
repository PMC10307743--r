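#' Plot a simulated trajectory
#'
#' Faceted time courses of the undamaged (`T`), sub-lethally damaged
#' (`TS`), dead (`TR`) and oxygen (`c`) variables, with irradiation windows
#' shaded when the trajectory was treated.
#'
#' @param object An `rt_trajectory`.
#' @param variables Which state variables to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rt_trajectory <- function(object, variables = c("T", "TS", "TR", "c"),
                                   ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t_min", variables)],
    -"t_min", names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = variables)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min / 1440, y = .data$value))
  sch <- attr(object, "schedule")
  if (!is.null(sch) && sch$n_fractions > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = sch$windows,
      ggplot2::aes(xmin = .data$start / 1440, xmax = .data$end / 1440,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6)
  }
  gg +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "volume fraction / oxygen") +
    ggplot2::theme_minimal()
}

#' Violin plot of cohort treatment response
#'
#' Distributions of `Delta_viable` and `Delta_total` (percent change between
#' the start of treatment and the last treatment week) across a cohort.
#'
#' @param object An `rt_cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rt_cohort_result <- function(object, ...) {
  ok <- object[is.na(object$error), , drop = FALSE]
  long <- tidyr::pivot_longer(ok[, c("id", "delta_viable", "delta_total")],
                              -"id", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "% change over treatment") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rt_cohort_result
#' @export
plot_cohort_response <- function(object, ...) autoplot.rt_cohort_result(object, ...)
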