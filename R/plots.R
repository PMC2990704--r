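#' Cost-effectiveness plane with the efficient frontier
#'
#' Plots each strategy's mean discounted QALYs against mean discounted
#' cost, connects the efficient frontier, and marks dominated strategies.
#'
#' @param object A `cea_result` from [incremental_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_result <- function(object, ...) {
  df <- object$table
  df$status <- dplyr::case_when(
    df$strongly_dominated ~ "strongly dominated",
    df$extendedly_dominated ~ "extendedly dominated",
    df$on_frontier ~ "efficient frontier",
    TRUE ~ "other"
  )
  frontier <- df[df$on_frontier, ]
  frontier <- frontier[order(frontier$cost), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = frontier, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Mean discounted QALYs per person",
                  y = "Mean discounted cost (CAN$ 2008) per person",
                  colour = NULL,
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatterplot
#'
#' One point per PSA draw: the incremental cost and incremental QALYs of
#' the comparison strategy versus its comparator. Points in the lower-right
#' quadrant are draws where the strategy is more effective and less costly.
#'
#' @param object A `psa_result` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(
      x = "Incremental QALYs per person",
      y = "Incremental cost (CAN$ 2008) per person",
      title = paste("Probabilistic sensitivity analysis:",
                    object$comparison[1], "vs", object$comparison[2])
    ) +
    ggplot2::theme_minimal()
}
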