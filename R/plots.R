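#' Forest plot of scan estimates
#'
#' Odds ratios with confidence intervals, one row per trait and method.
#'
#' @param object An `mr_scan`.
#' @param methods Methods to display (default all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_scan <- function(object, methods = NULL, ...) {
  est <- tidy(object)
  if (!is.null(methods)) est <- dplyr::filter(est, .data$method %in% methods)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$or, y = .data$trait_id,
                                    colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = "Method") +
    ggplot2::theme_minimal()
}

#' Scatter plot of harmonized effects with fitted causal slopes
#'
#' Per-variant outcome versus exposure effects with the IVW line through
#' the origin and, when estimable, the MR-Egger line with its intercept.
#'
#' @param pairs Harmonized pairs (kept rows are used).
#' @param n_boot,seed Passed to the weighted-median fit (shown in the
#'   caption only).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(pairs, n_boot = 200, seed = 42) {
  pairs <- kept_pairs(pairs)
  s <- sign(pairs$beta_exp)
  df <- tibble::tibble(bx = abs(pairs$beta_exp), by = pairs$beta_out * s,
                       se_out = pairs$se_out)
  ivw <- mr_ivw(pairs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - 1.96 * .data$se_out,
                                        ymax = .data$by + 1.96 * .data$se_out),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta, colour = "#2166ac") +
    ggplot2::labs(x = "Variant effect on exposure",
                  y = "Variant effect on outcome",
                  caption = sprintf("IVW slope %.3f", ivw$beta)) +
    ggplot2::theme_minimal()
  if (nrow(df) >= 3) {
    eg <- mr_egger(pairs)
    p <- p + ggplot2::geom_abline(intercept = eg$intercept$beta,
                                  slope = eg$slope$beta,
                                  colour = "#b2182b", linetype = "dashed")
  }
  p
}

#' Leave-one-out influence plot
#'
#' @param loo Tibble from [mr_leave_one_out()].
#' @param full Optional full-set `mr_estimate` drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo, full = NULL) {
  p <- ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta,
                                         y = stats::reorder(.data$snp_id, .data$beta))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                                          xmax = .data$beta + 1.96 * .data$se)) +
    ggplot2::labs(x = "IVW estimate omitting variant", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(full)) {
    p <- p + ggplot2::geom_vline(xintercept = full$beta, colour = "#2166ac",
                                 linetype = "dashed")
  }
  p
}

#' Mediation decomposition bar chart
#'
#' Total, direct and indirect effects per exposure-mediator pair.
#'
#' @param object An `mr_mediation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_mediation <- function(object, ...) {
  res <- tidy(object)
  long <- res |>
    dplyr::mutate(pair = paste(.data$exposure_id, "→", .data$mediator_id)) |>
    tidyr::pivot_longer(cols = c("beta_total", "direct", "indirect"),
                        names_to = "component", values_to = "effect")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$effect, y = .data$pair,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Effect (log-odds)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
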