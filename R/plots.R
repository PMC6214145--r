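# Plot-ready views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression table
#'
#' log2 fold change against -log10 p, colored by the significance call and
#' direction, with the class thresholds drawn as reference lines.
#'
#' @param de A `cernet_de` table.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de) {
  thr <- attr(de, "thresholds")
  status <- ifelse(!de$significant, "not significant",
                   ifelse(de$direction == "up", "up", "down"))
  df <- mutate(as_tibble(de), status = factor(status,
               levels = c("up", "down", "not significant")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                        colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            `not significant` = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(-log2(thr$fc_min), log2(thr$fc_min)),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_hline(yintercept = -log10(thr$p_max),
                          linetype = "dashed", colour = "grey40")
  }
  p
}

#' @method autoplot cernet_de
#' @export
autoplot.cernet_de <- function(object, ...) plot_volcano(object)

#' Bar chart of the top enriched terms
#'
#' @param enr Result of [hypergeometric_enrichment()].
#' @param top_n Number of terms to show (default 10, by enrichment score).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enr, top_n = 10) {
  df <- head(arrange(as_tibble(enr), dplyr::desc(.data$score)), top_n)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$term_name)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::labs(x = "enrichment score (-log10 p)", y = NULL) +
    ggplot2::theme_minimal()
}
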