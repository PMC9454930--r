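#' Plot a cost-effectiveness acceptability curve
#'
#' @param object An `ascr_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot: probability that screening is cost-effective against the
#'   willingness-to-pay threshold.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ascr_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$prob_cost_effective)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::scale_x_continuous(labels = function(x) format(x, big.mark = " ")) +
    ggplot2::labs(x = "Willingness to pay (EUR per QALY)",
                  y = "Probability screening is cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane of a probabilistic analysis
#'
#' Scatter of per-draw incremental QALYs against incremental costs, with the
#' deterministic point estimate marked.
#'
#' @param object An `ascr_psa` from [run_psa()].
#' @param wtp Willingness-to-pay threshold drawn as a reference line
#'   (EUR per QALY); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ascr_psa <- function(object, wtp = 50000, ...) {
  d <- object$draws
  pt <- object$point$incremental
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly,
                                       y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::annotate("point", x = pt$delta_qaly, y = pt$delta_cost,
                      colour = "firebrick", size = 2.5) +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost per person (EUR)",
                  title = sprintf("Cost-effectiveness plane (%s, %d draws)",
                                  object$population, object$n_draws)) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    g <- g + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed", colour = "grey30")
  }
  g
}

#' Plot a one-way sensitivity (tornado) analysis
#'
#' Horizontal bars from the ICER at each parameter's low bound to the ICER at
#' its high bound, widest swing on top, with the base-case ICER as a vertical
#' reference line.
#'
#' @param object An `ascr_tornado` from [tornado_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ascr_tornado <- function(object, ...) {
  d <- tibble::as_tibble(object) %>%
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "icer_base"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (EUR per QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER") +
    ggplot2::theme_minimal()
}

#' Plot a cohort trace
#'
#' State occupancy per cycle as stacked areas over age.
#'
#' @param object An `ascr_trace` from [run_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ascr_trace <- function(object, ...) {
  d <- tibble::as_tibble(object) %>%
    tidyr::pivot_longer(dplyr::all_of(health_states()),
                        names_to = "state", values_to = "occupancy") %>%
    mutate(state = factor(.data$state, levels = health_states()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                  fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = "Age (years)", y = "State occupancy",
                  fill = "State", title = "Cohort trace") +
    ggplot2::theme_minimal()
}

#' @export
plot.ascr_ceac <- function(x, ...) print(autoplot.ascr_ceac(x, ...))

#' @export
plot.ascr_psa <- function(x, ...) print(autoplot.ascr_psa(x, ...))

#' @export
plot.ascr_tornado <- function(x, ...) print(autoplot.ascr_tornado(x, ...))

#' @export
plot.ascr_trace <- function(x, ...) print(autoplot.ascr_trace(x, ...))
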