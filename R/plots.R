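# ggplot2 graphics for result objects.

#' Plot the random-trial fold distribution of a fold-difference test
#'
#' Histogram of per-trial folds with the mean fold marked.
#'
#' @param object A `fold_diff`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fold_diff
#' @export
autoplot.fold_diff <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_fold, colour = "firebrick") +
    ggplot2::labs(
      x = "observed / random fold",
      y = "trials",
      title = sprintf(
        "%s: mean fold %.2f (sd %.2f), %s",
        object$mode, object$mean_fold, object$sd_fold, object$direction
      )
    )
}

#' Bar chart of fold differences for several gene-set tests
#'
#' Mean fold with standard-deviation error bars, one bar per test, in the
#' style of group-comparison fold plots.
#'
#' @param folds Named list of `fold_diff` objects.
#' @return A ggplot.
#' @export
plot_fold_bars <- function(folds) {
  stopifnot(length(folds) >= 1, !is.null(names(folds)))
  df <- bind_rows(lapply(folds, glance), .id = "test")
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$test, y = .data$mean_fold, fill = .data$direction)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_fold - .data$sd_fold,
        ymax = .data$mean_fold + .data$sd_fold
      ),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fold difference vs random sets")
}

#' Heat map of a scaled enrichment matrix
#'
#' @param object A `heatmap_matrix` from [scale_log_pvalues()].
#' @param cluster Reorder context columns by [cluster_contexts()] when there
#'   are at least two contexts.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot heatmap_matrix
#' @export
autoplot.heatmap_matrix <- function(object, cluster = TRUE, ...) {
  m <- unclass(object)
  if (cluster && ncol(m) >= 2) {
    m <- m[, cluster_contexts(object)$order, drop = FALSE]
  }
  df <- as_tibble(m, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "context", values_to = "value")
  df$context <- factor(df$context, levels = colnames(m))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$context, y = .data$term, fill = .data$value)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "firebrick", limits = c(0, 1),
      name = "scaled -log10 p"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
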