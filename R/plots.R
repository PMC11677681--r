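#' Plot a segment-length histogram
#'
#' @param object A `pssp_seglen_histogram` from [segment_length_histogram()].
#' @param ... Unused.
#' @return A ggplot object: segment counts per length interval.
#' @exportS3Method ggplot2::autoplot
autoplot.pssp_seglen_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "segment length interval (residues)",
                  y = "number of segments",
                  title = "Secondary-structure segment length pattern") +
    ggplot2::theme_minimal()
}

#' Plot a normalized confusion matrix
#'
#' @param object A `pssp_evaluation` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot heatmap of the normalized confusion matrix.
#' @exportS3Method ggplot2::autoplot
autoplot.pssp_evaluation <- function(object, ...) {
  m <- unclass(object$confusion)
  df <- tibble::tibble(
    observed = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    predicted = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    fraction = as.numeric(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fraction)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = "Normalized confusion matrix") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object An `mtl_fit` or `hta_fit`.
#' @param ... Unused.
#' @return A ggplot of per-epoch losses and the validation metric.
#' @exportS3Method ggplot2::autoplot
autoplot.mtl_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -c("epoch", "lr"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", title = "Training history") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mtl_fit
#' @exportS3Method ggplot2::autoplot
autoplot.hta_fit <- autoplot.mtl_fit

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
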