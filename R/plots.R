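# ggplot2 displays for the three result types.

#' Plot empirical versus nominal FDR
#'
#' One panel per scheme; the dashed identity line is the target an FDR-
#' controlling procedure should stay on or below.
#'
#' @param object A `semibench_eval` in gold-standard mode.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot semibench_eval
#' @export
autoplot.semibench_eval <- function(object, ...) {
  if (object$mode != "gold") {
    return(plot_type1(object))
  }
  df <- object$summary |>
    dplyr::mutate(n_label = paste0("n = ", .data$n1, "+", .data$n2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$fdr,
                                   colour = .data$method,
                                   shape = .data$n_label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$method,
                                                        .data$n_label))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$fdr - 2 * .data$fdr_se, 0),
                   ymax = .data$fdr + 2 * .data$fdr_se),
      width = 0
    ) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = "nominal FDR level", y = "empirical FDR",
                  colour = "method", shape = "sample size") +
    ggplot2::theme_minimal()
}

plot_type1 <- function(object) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$level, y = .data$type1,
                               colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = "raw level", y = "per-gene type-I error") +
    ggplot2::theme_minimal()
}

#' Plot power against sample size
#'
#' @param report A `semibench_eval` in gold-standard mode with at least two
#'   grid sizes.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(report) {
  df <- power_vs_n_curve(report)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n1, y = .data$power,
                                   colour = .data$method,
                                   linetype = factor(.data$level))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$power - 2 * .data$power_se, 0),
                   ymax = pmin(.data$power + 2 * .data$power_se, 1)),
      width = 0
    ) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = "samples per group", y = "empirical power",
                  linetype = "nominal FDR") +
    ggplot2::theme_minimal()
}

#' Plot the library-size confounding diagnostic
#'
#' Scatter of the per-gene donor/recipient log library-size imbalance against
#' the signed group difference of the analyzed values.
#'
#' @param object A `confounding_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot confounding_report
#' @export
autoplot.confounding_report <- function(object, ...) {
  sub <- if (object$no_imbalance) {
    "all library sizes equal: no imbalance"
  } else {
    sprintf("Spearman rho = %.3f (permutation p = %.3g)", object$rho,
            object$p_perm)
  }
  ggplot2::ggplot(object$per_gene, ggplot2::aes(x = .data$d, y = .data$s)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick",
                         se = FALSE) +
    ggplot2::labs(
      x = "donor/recipient log library-size imbalance d",
      y = "signed group difference of analyzed values s",
      title = "Library-size confounding across null genes",
      subtitle = sub
    ) +
    ggplot2::theme_minimal()
}
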