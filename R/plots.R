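# ggplot2 displays for fitted curves and cohort reports.

#' Plot an observed curve with its model fit
#'
#' @param object a `dce_fit` from [fit_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dce_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$data, c("observed", "fitted"),
                           names_to = "series", values_to = "conc")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$conc,
                                  colour = .data$series,
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (mM)",
                  title = sprintf("%s model fit (rss = %.3g)",
                                  object$model, object$rss)) +
    ggplot2::theme_minimal()
}

#' Boxplots of kinetic parameters by molecular group
#'
#' @param object a `dce_report` from [build_report()].
#' @param ... unused.
#' @return A ggplot faceted by parameter (log10 y scale).
#' @export
autoplot.dce_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$cohort, dplyr::all_of(dce_param_names),
                           names_to = "parameter", values_to = "value")
  d$group <- ifelse(d$idh == "wild-type", "wild-type",
                    paste0("mutant-", d$codeletion))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "reported units")
}

#' Empirical ROC curves for one comparison
#'
#' @param report a `dce_report`.
#' @param comparison `"idh"` or `"codeletion"`.
#' @param parameters parameter names to draw (default: all 9).
#' @return A ggplot.
#' @export
plot_roc_curves <- function(report, comparison = c("idh", "codeletion"),
                            parameters = dce_param_names) {
  comparison <- match.arg(comparison)
  cohort <- if (comparison == "idh") report$cohort
            else dplyr::filter(report$cohort, .data$idh == "mutation")
  grp_col <- if (comparison == "idh") "idh" else "codeletion"
  dirs <- report$meta$directions[[comparison]]
  curves <- purrr::map(parameters, function(pn) {
    pos <- dirs[[pn]]
    s <- cohort[[pn]]
    is_pos <- cohort[[grp_col]] == pos
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    tibble::tibble(parameter = pn,
                   fpr = vapply(thr, function(th) mean(s[!is_pos] >= th), 1),
                   tpr = vapply(thr, function(th) mean(s[is_pos] >= th), 1))
  })
  ggplot2::ggplot(dplyr::bind_rows(curves),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$parameter)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC: %s", comparison)) +
    ggplot2::theme_minimal()
}
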