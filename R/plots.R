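# ggplot2 displays for the main result types

#' Bar plot of screen calls
#'
#' Max BRET ratio per library protein, coloured by call, with the calling
#' threshold drawn as a dashed line.
#'
#' @param calls Call tibble from [bret_call()] / [run_screen()].
#' @param bait Bait symbol (bars show the partner protein).
#' @param threshold Threshold line.
#' @return A ggplot object.
#' @export
plot_screen_calls <- function(calls, bait = "PEX26", threshold = 0.094) {
  bait <- norm_symbol(bait)
  df <- calls |>
    mutate(partner = ifelse(.data$pair_a == bait, .data$pair_b, .data$pair_a))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$partner, -.data$max_ratio),
    y = .data$max_ratio, fill = .data$positive)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#e6b800", `FALSE` = "#3b6fb6"),
                               name = "interaction") +
    ggplot2::labs(x = NULL, y = "max BRET ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Tile plot of the variant edge-loss matrix
#'
#' @param matrix Wide variant-by-partner matrix (fixture layout).
#' @return A ggplot object.
#' @export
plot_loss_matrix <- function(matrix) {
  long <- matrix |>
    tidyr::pivot_longer(-"variant_id", names_to = "partner", values_to = "call") |>
    mutate(call = factor(.data$call, levels = c(1, 0),
                         labels = c("maintained", "lost")))
  ggplot2::ggplot(long, ggplot2::aes(.data$partner, .data$variant_id,
                                     fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(maintained = "#e6b800",
                                          lost = "#3b6fb6"),
                               na.value = "grey85", name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' Heatmap of edgetic perturbations per disease phenotype
#'
#' @param heat Tibble from [perturbation_phenotype_heatmap()].
#' @return A ggplot object.
#' @export
plot_perturbation_heatmap <- function(heat) {
  ggplot2::ggplot(heat, ggplot2::aes(.data$phenotype, .data$variant_id,
                                     fill = .data$n_perturbed)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 name = "perturbed\ninteractions") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' @export
autoplot.ppi_score_cor <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(.data[[object$n_ppi]],
                                   .data[[object$score]])) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2.5, colour = "#3b6fb6") +
    ggplot2::labs(
      x = "maintained interactions (n_PPI)", y = "biochemical score",
      subtitle = sprintf("Pearson r = %.2f, p = %.2g", object$r,
                         object$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.variant_clustering <- function(object, ...) {
  hc <- object$hclust
  # dendrogram segments from the merge tree
  n <- length(hc$order)
  xpos <- setNames(seq_len(n), hc$labels[hc$order])
  node_x <- numeric(nrow(hc$merge))
  segs <- list()
  coord <- function(i) {
    if (i < 0) c(xpos[hc$labels[-i]], 0) else c(node_x[i], hc$height[i])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- coord(hc$merge[i, 1]); b <- coord(hc$merge[i, 2])
    h <- hc$height[i]
    node_x[i] <- mean(c(a[1], b[1]))
    segs[[i]] <- tibble(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, b[2]),
      yend = c(h, h, h))
  }
  segdf <- bind_rows(segs)
  labdf <- tibble(label = names(xpos), x = unname(xpos))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segdf,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labdf,
                       ggplot2::aes(.data$x, -0.02 * max(hc$height),
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.45 * max(hc$height), NA)) +
    ggplot2::labs(y = paste0("height (", object$distance, ")"), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Stacked bars of building-block shares per variant
#'
#' @param impacts Tibble binding [building_block_impact()] results with a
#'   `variant_id` column.
#' @return A ggplot object.
#' @export
plot_block_impact <- function(impacts) {
  ggplot2::ggplot(impacts, ggplot2::aes(.data$variant_id, .data$pct,
                                        fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
    ggplot2::labs(x = NULL, y = "share of remaining edges (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
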