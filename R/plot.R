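# ggplot2 helpers for quick QC of masks, compositions and training runs.

#' Plot a label mask
#'
#' @param mask a [label_mask()].
#' @return A ggplot object (raster of class colors with a legend).
#' @export
plot_label_mask <- function(mask) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- expand.grid(y = seq_len(nrow(mask)), x = seq_len(ncol(mask)))
  df$class <- factor(names(pattern_classes())[as.vector(unclass(mask)) + 1L],
                     levels = names(pattern_classes()))
  pal <- setNames(mask_palette(), names(pattern_classes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "pattern")
}

#' Plot a pattern composition
#'
#' @param comp a `pattern_composition`.
#' @return A ggplot bar chart of the pooled proportions.
#' @export
plot_composition <- function(comp) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- tidy(comp)
  pal <- setNames(mask_palette()[-1L], pattern_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$proportion,
                                   fill = .data$pattern)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = NULL, y = "proportion of tumor pixels") +
    ggplot2::theme_minimal()
}

#' Plot a training loss history
#'
#' @param history the `history` tibble from [train_network()].
#' @return A ggplot line chart of per-epoch mean loss.
#' @export
plot_loss_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}
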