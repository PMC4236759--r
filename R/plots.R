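#' Plot per-library expression distributions
#'
#' Log10 CPM distributions of expressed genes per library, with the
#' expressed-gene counts in the strip labels.
#'
#' @param object An [expression_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot expression_profile
#' @export
autoplot.expression_profile <- function(object, ...) {
  dat <- dplyr::filter(object, .data$cpm > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$library, y = .data$cpm,
                                    fill = .data$expressed)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "library", y = "CPM",
                  title = "Expression by library",
                  fill = "expressed (CPM ≥ threshold)") +
    ggplot2::theme_minimal()
}

#' Plot trajectory class composition
#'
#' Bar chart of trajectory classes split by the gene's direction in the
#' first contrast - the visual counterpart of the reversal summary.
#'
#' @param object A [classify_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_calls
#' @export
autoplot.trajectory_calls <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$first_status))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$first_status,
                                    fill = .data$class)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = "direction in first contrast", y = "genes",
                  title = "Expression trajectories across contrasts") +
    ggplot2::theme_minimal()
}

#' Plot top enriched terms
#'
#' Dot plot of the most significant terms: -log10 FDR against overlap size.
#'
#' @param object An [enrich()] result.
#' @param n_terms Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot go_enrichment
#' @export
autoplot.go_enrichment <- function(object, n_terms = 15, ...) {
  dat <- head(dplyr::arrange(as_tibble(object), .data$p), n_terms)
  dat$term <- factor(dat$term, levels = rev(dat$term))
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(.data$fdr), y = .data$term,
                                    size = .data$k)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL, size = "overlap k",
                  title = "Term over-representation") +
    ggplot2::theme_minimal()
}
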