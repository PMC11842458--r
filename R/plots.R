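#' Forest plot of a pooled association
#'
#' Sample-level back-transformed estimates with 95% CIs and the pooled
#' diamond for one of the twelve associations of a [run_analysis()] report.
#'
#' @param object A `lagtriad_report`.
#' @param association One association key (see [association_labels()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lagtriad_report
#' @export
autoplot.lagtriad_report <- function(object, association = "b_x_lagged", ...) {
  stopifnot(association %in% association_labels()$association)
  d <- dplyr::filter(object$forest, .data$association == !!association)
  if (nrow(d) == 0) abort(paste0("no forest data for ", association))
  pooled <- dplyr::filter(object$meta, .data$association == !!association)
  lab <- association_labels()$label[association_labels()$association == association]
  d <- dplyr::mutate(d, sample_id = stats::reorder(.data$sample_id, .data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$sample_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = pooled$estimate, colour = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = 1 / (.data$ci_high - .data$ci_low)),
                        shape = 15, show.legend = FALSE) +
    ggplot2::annotate(
      "errorbarh", y = 0, xmin = pooled$ci_low, xmax = pooled$ci_high,
      height = 0.4, colour = "steelblue", linewidth = 1
    ) +
    ggplot2::labs(
      title = paste0("Forest plot: ", lab),
      subtitle = sprintf("pooled %.3f (%.3f; %.3f), K = %d",
                         pooled$estimate, pooled$ci_low, pooled$ci_high, pooled$K),
      x = "estimate", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Predicted-trajectory panels under the three conditionings
#'
#' The diagnostic picture of spuriousness: for each construct direction,
#' the predicted standardized outcome at waves 1 and 2 for individuals at
#' low / mean / high predictor scores, conditioning on the initial outcome,
#' on the subsequent outcome, and not at all. A spurious association shows a
#' decreasing predictor effect in the first panel but increasing ones in the
#' other two.
#'
#' @param data One-row data frame holding a full correlation sextet.
#' @param z_levels Predictor standard scores.
#' @return A ggplot object faceted by direction and conditioning.
#' @examples
#' plot_trajectories(pooled_to_sextet(se_ed_pooled()))
#' @export
plot_trajectories <- function(data, z_levels = c(-1, 0, 1)) {
  grids <- tidyr::expand_grid(
    direction = c("x_on_y", "y_on_x"),
    conditioning = c("initial", "subsequent", "none")
  )
  d <- purrr::pmap(grids, function(direction, conditioning) {
    out <- predicted_trajectories(data, conditioning, z_levels, direction)
    out$direction <- direction
    out
  })
  d <- dplyr::bind_rows(d)
  d <- dplyr::mutate(
    d,
    direction = factor(.data$direction, c("x_on_y", "y_on_x"),
                       c("outcome Y, predictor X1", "outcome X, predictor Y1")),
    conditioning = factor(.data$conditioning, c("initial", "subsequent", "none")),
    z = factor(.data$z)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$predicted,
                                  colour = .data$z, group = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = c(1, 2), labels = c("T1", "T2")) +
    ggplot2::facet_grid(direction ~ conditioning) +
    ggplot2::labs(x = NULL, y = "predicted standardized outcome",
                  colour = "predictor Z") +
    ggplot2::theme_minimal()
}
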