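#' Plot a flow-volume trace with its AEX polygon
#'
#' @param object An `aex_fv_curve` (e.g. from [make_flow_volume_trace()]).
#' @param landmarks Optional landmarks; if given, the order-4 node polyline
#'   is overlaid so the scooped area and its polygonal approximation can be
#'   compared visually.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aex_fv_curve <- function(object, landmarks = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$volume_L, y = .data$flow_L_s)) +
    ggplot2::geom_area(alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.6, colour = "steelblue4") +
    ggplot2::labs(x = "Exhaled volume (L)", y = "Flow (L/s)",
                  title = "Expiratory flow-volume curve")
  if (!is.null(landmarks)) {
    nodes <- aex_nodes(landmarks, order = 4)
    p <- p +
      ggplot2::geom_line(data = nodes,
                         ggplot2::aes(x = .data$volume, y = .data$flow),
                         linetype = 2, colour = "grey30") +
      ggplot2::geom_point(data = nodes,
                          ggplot2::aes(x = .data$volume, y = .data$flow),
                          colour = "grey30")
  }
  p
}

#' Bar chart of total-effect importance shares
#'
#' @param object An `aex_importance` from [total_effects()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aex_importance <- function(object, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), .data$total_effect)
  d$factor <- factor(d$factor, levels = d$factor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_effect, y = .data$factor)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Total effect (% of output variance)", y = NULL,
                  title = "Input importance (dependent resampled inputs)")
}

#' Observed vs predicted diagnostic for a fitted model
#'
#' @param model A fitted model with a `predict` method.
#' @param data Cohort table with the outcome column.
#' @param outcome Outcome column name.
#' @return A ggplot of predictions against observations with the identity
#'   line.
#' @export
plot_observed_predicted <- function(model, data, outcome = "aex") {
  d <- tibble::tibble(observed = data[[outcome]],
                      predicted = predict(model, data))
  m <- eval_metrics(observed = d$observed, predicted = d$predicted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(
      x = "Observed AEX (L\u00b2/s)", y = "Predicted AEX (L\u00b2/s)",
      title = sprintf("R\u00b2 = %.3f, RASE = %.2f, AAE = %.2f",
                      m$r2, m$rase, m$aae)
    )
}
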