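#' Plot a 2-D embedding colored by a per-cell variable
#'
#' @param embedding an [embed_tsne()] result.
#' @param color optional tibble (`cell_id`, value column) or vector named by
#'   cell id; e.g. cluster labels or a signature score.
#' @param color_name legend title.
#' @return a ggplot.
#' @export
plot_embedding <- function(embedding, color = NULL, color_name = "value") {
  df <- as_tibble(embedding)
  if (!is.null(color)) {
    if (is.data.frame(color)) {
      val_col <- setdiff(names(color), "cell_id")[1]
      df <- dplyr::left_join(df, color[, c("cell_id", val_col)], by = "cell_id")
      names(df)[names(df) == val_col] <- ".color"
    } else {
      df$.color <- color[df$cell_id]
    }
    ggplot2::ggplot(df, ggplot2::aes(
      .data$tsne1, .data$tsne2,
      color = .data$.color
    )) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = color_name) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$tsne1, .data$tsne2)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot embedding_2d
#' @export
autoplot.embedding_2d <- function(object, ...) plot_embedding(object, ...)

#' Signature-score heat map on an embedding
#'
#' The per-cell displayed score `H_c` painted on the 2-D embedding, one
#' panel per signature — the standard way signature activity is displayed
#' over a t-SNE projection.
#'
#' @param embedding an [embed_tsne()] result.
#' @param scores a long score table (`cell_id`, `signature`, `score`), e.g.
#'   from [score_signatures()].
#' @return a ggplot, faceted by signature.
#' @export
plot_signature_map <- function(embedding, scores) {
  df <- dplyr::inner_join(
    as_tibble(embedding), as_tibble(scores),
    by = "cell_id"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$tsne1, .data$tsne2,
    color = .data$score
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::facet_wrap(~signature) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = "H") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a grouped differential-expression table
#'
#' log2 fold change against -log10 p, with the flagged top set highlighted.
#'
#' @param degs a [find_degs_grouped()] result.
#' @return a ggplot.
#' @export
plot_volcano <- function(degs) {
  df <- as_tibble(degs)
  df$p_plot <- pmax(df$p_value, 1e-300)
  ggplot2::ggplot(df, ggplot2::aes(
    .data$log2_fc, -log10(.data$p_plot),
    color = .data$in_top
  )) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3")) +
    ggplot2::labs(
      x = "log2(fold change)", y = "-log10(P value)", color = "top set"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) plot_volcano(object)

#' Jitter plot of per-cell scores by group
#'
#' @param scores tibble with `cell_id` and a score column.
#' @param groups tibble (`cell_id`, `group`) or vector named by cell id.
#' @param score_col name of the score column (default `"score"`).
#' @return a ggplot.
#' @export
plot_score_jitter <- function(scores, groups, score_col = "score") {
  df <- as_tibble(scores)
  if (is.data.frame(groups)) {
    df <- dplyr::left_join(df, groups, by = "cell_id")
  } else {
    df$group <- groups[df$cell_id]
  }
  ggplot2::ggplot(df, ggplot2::aes(
    .data$group, .data[[score_col]],
    color = .data$group
  )) +
    ggplot2::geom_jitter(width = 0.25, size = 0.8, show.legend = FALSE) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar",
      width = 0.5, color = "black", linewidth = 0.3
    ) +
    ggplot2::theme_minimal()
}
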