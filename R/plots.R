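#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot ep_gene_table
#' @export
autoplot.ep_gene_table <- function(object, ...) {
  d <- as_tibble(object)
  d$rank <- seq_len(nrow(d))
  d$neglog_q <- -log10(pmax(d$best_q, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$neglog_q,
                                  size = .data$sumCC,
                                  colour = .data$de_direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = "ranked I-P interaction", y = "-log10(best q)",
                  size = "sumCC", colour = "direction",
                  title = "E-P genes by interaction significance") +
    ggplot2::theme_minimal()
}

#' @method autoplot signal_matrix
#' @export
autoplot.signal_matrix <- function(object, clusters = NULL, ...) {
  d <- tidy(object)
  if (!is.null(clusters)) {
    d$cluster <- factor(clusters$cluster[d$region])
    d <- d |>
      dplyr::group_by(.data$track, .data$cluster, .data$position) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$value,
                                         colour = .data$cluster))
  } else {
    d <- d |>
      dplyr::group_by(.data$track, .data$position) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$value))
  }
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~track, scales = "free_y") +
    ggplot2::labs(x = "distance from motif center (bp)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Hockey-stick plot of ranked enhancer signal
#'
#' @param rose Output of [call_super_enhancers()].
#' @return A ggplot.
#' @export
plot_enhancer_ranking <- function(rose) {
  d <- as_tibble(rose)
  d <- d[order(d$signal), ]
  d$ascending_rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ascending_rank, y = .data$signal,
                                  colour = .data$is_super)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "enhancers ranked by signal", y = "signal",
                  colour = "super-enhancer") +
    ggplot2::theme_minimal()
}

#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  d <- as_tibble(object)
  d$set <- stats::reorder(d$set, d$nes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nes, y = .data$set,
                                  fill = .data$adj_p < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  fill = "adj. p < 0.05") +
    ggplot2::theme_minimal()
}

#' @method autoplot module_score_result
#' @export
autoplot.module_score_result <- function(object, groups = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(groups)) {
    d$group <- groups
    ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$score)) +
      ggplot2::geom_violin(fill = "steelblue", alpha = 0.4) +
      ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
      ggplot2::labs(y = "module score") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
      ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
      ggplot2::labs(x = "module score", y = "cells") +
      ggplot2::theme_minimal()
  }
}
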