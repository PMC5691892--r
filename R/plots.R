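#' Plot a GSEA running enrichment sum
#'
#' The classic enrichment plot: the weighted Kolmogorov-Smirnov running sum
#' along the ranked list, with a rug of gene-set hit positions and the ES
#' peak marked.
#'
#' @inheritParams enrichment_score
#' @return A ggplot object.
#' @export
plot_running_sum <- function(ranked, set, weight_p = 1) {
  es <- enrichment_score(ranked, set, weight_p = weight_p)
  n <- length(es$running_sum)
  hits <- which(ranked$gene %in% set_genes(set))
  df <- tibble::tibble(position = seq_len(n), running_sum = es$running_sum)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = tibble::tibble(position = hits),
                      ggplot2::aes(x = .data$position), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::annotate("point", x = es$peak_position, y = es$es,
                      colour = "#d7301f") +
    ggplot2::labs(x = "rank position", y = "running enrichment sum",
                  subtitle = sprintf("ES = %.3f at position %d", es$es,
                                     es$peak_position)) +
    ggplot2::theme_minimal()
}

#' Box plot of fit scores by group
#'
#' @param x A `fit_tbl` from [fit_score()].
#' @param ... Unused.
#' @return A ggplot object with the moderate/high fit thresholds as dashed
#'   lines.
#' @export
autoplot.fit_tbl <- function(x, ...) {
  if (is.null(x[["group"]])) {
    stop("fit table has no group column", call. = FALSE)
  }
  thr <- attr(x, "thresholds")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$group, y = .data$fit)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$fit_class),
                         width = 0.15, size = 1.6) +
    ggplot2::geom_hline(yintercept = unname(thr), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(none = "grey60", moderate = "#fd8d3c", high = "#d7301f"),
      drop = FALSE) +
    ggplot2::labs(x = NULL, y = "signature fit score",
                  colour = "fit class") +
    ggplot2::theme_minimal()
}

#' Correlation matrix plot
#'
#' Tile rendering of a pairwise Pearson matrix: fill encodes r (blue
#' negative, red positive), asterisks mark pairs beyond the critical r at
#' the chosen significance level.
#'
#' @param x A `correlation_result` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_result <- function(x, ...) {
  df <- tidyr::expand_grid(gene_1 = x$panel, gene_2 = x$panel)
  df$r <- as.vector(t(x$r))
  df$significant <- as.vector(t(x$significant))
  df$gene_1 <- factor(df$gene_1, levels = x$panel)
  df$gene_2 <- factor(df$gene_2, levels = rev(x$panel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_1, y = .data$gene_2,
                                   fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  subtitle = sprintf("n = %d, |r| > %.2f marked *", x$n,
                                     x$r_crit)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
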