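#' Plot a reduction ledger
#'
#' Bar chart of records removed per curation rule, in pipeline order.
#'
#' @param ledger Ledger tibble (from [curate()] or [run_filters()]).
#' @return A ggplot object.
#' @export
plot_reduction_ledger <- function(ledger) {
  ledger$rule <- factor(ledger$rule, levels = ledger$rule)
  ggplot2::ggplot(ledger, ggplot2::aes(x = .data$rule, y = .data$n_removed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_removed), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "records removed",
                  title = "Dataset reduction per curation rule") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Scatter plot of predictions against targets
#'
#' @param scatter Long tibble with `task`, `prediction`, `target` (as
#'   produced by [benchmark_harness()]).
#' @return A ggplot object, faceted by task.
#' @export
plot_prediction_scatter <- function(scatter) {
  d <- scatter[!is.na(scatter$target), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$target, y = .data$prediction)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "experimental affinity (p-scale)",
                  y = "predicted affinity") +
    ggplot2::theme_minimal()
}

#' Autoplot method for metric reports
#'
#' RMSE per task and split, with the derived 95% prediction interval
#' half-width (`1.96 * RMSE`) as an error-bar annotation.
#'
#' @param object A `dta_metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dta_metric_report
#' @export
autoplot.dta_metric_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$task, y = .data$rmse,
                                       fill = .data$split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "RMSE (log10 orders)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot method for ensembles: training curves
#'
#' Validation-loss trajectory per cross-validation fold.
#'
#' @param object A `dta_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dta_ensemble
#' @export
autoplot.dta_ensemble <- function(object, ...) {
  d <- dplyr::bind_rows(lapply(seq_along(object$submodels), function(i) {
    m <- object$submodels[[i]]$manifest
    m$fold <- factor(i)
    m
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$val_loss,
                                  colour = .data$fold)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "validation loss", x = "epoch") +
    ggplot2::theme_minimal()
}
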