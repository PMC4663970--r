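# ggplot2 displays for the three result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a glider response table
#'
#' @param object A [glider_response()] table (optionally with a `model`
#'   column, faceted).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glider_response_table <- function(object, ...) {
  d <- dplyr::mutate(object,
                     condition = paste0(.data$type,
                                        ifelse(.data$parity > 0, " +", " -")))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$condition,
                                       y = .data$response)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$response - .data$sem,
                                        ymax = .data$response + .data$sem),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "response (positive 2-point = 1)") +
    ggplot2::theme_minimal()
  if ("model" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$model))
  }
  p
}

#' Accuracy bars across the model hierarchy
#'
#' @param object An accuracy table from [run_fit()].
#' @param ... Unused.
#' @export
autoplot.emd_accuracy <- function(object, ...) {
  d <- dplyr::mutate(object, architecture = factor(.data$architecture,
                                                   levels = .data$architecture))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$architecture, y = .data$r_test)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r_test - .data$accuracy_sd,
                                        ymax = .data$r_test + .data$accuracy_sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "test correlation with velocity") +
    ggplot2::theme_minimal()
}

#' Support size versus accuracy of a lasso scan
#'
#' @param object An [`emd_lasso`][lasso_scan] tibble.
#' @param ... Unused.
#' @export
autoplot.emd_lasso <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_support,
                                       y = .data$r_test)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "r_full"),
                        linetype = "dashed") +
    ggplot2::labs(x = "predictors in support",
                  y = "test correlation (OLS refit)") +
    ggplot2::theme_minimal()
}
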