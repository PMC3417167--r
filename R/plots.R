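#' Plot axial slices of a stat map
#'
#' @param object A [stat_map()].
#' @param slices Axial (z) slice indices; default: four evenly spaced.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stat_map <- function(object, slices = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slices)) {
    slices <- unique(round(seq(d[3] * 0.2, d[3] * 0.8, length.out = 4)))
  }
  df <- purrr::map_dfr(slices, function(zi) {
    tibble::tibble(
      x = rep(seq_len(d[1]), times = d[2]),
      y = rep(seq_len(d[2]), each = d[1]),
      z = zi,
      value = as.vector(object$values[, , zi])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s map (%s)", object$kind, object$feature),
      fill = object$kind
    ) +
    ggplot2::theme_minimal()
}

#' Plot a connectivity graph (circular layout)
#'
#' Link thickness encodes the mean correlation, node size the degree.
#'
#' @param object A `connectivity_graph`.
#' @param modules Optional named module assignment for node color (e.g. from
#'   [detect_communities()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_graph <- function(object, modules = NULL, ...) {
  n <- length(object$nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  layout <- tibble::tibble(
    node = object$nodes, x = cos(theta), y = sin(theta),
    degree = object$degree$degree
  )
  if (!is.null(modules)) {
    layout$module <- factor(modules[layout$node])
  } else {
    layout$module <- factor(1)
  }
  ed <- object$edges |>
    dplyr::mutate(
      x = layout$x[match(.data$node_a, layout$node)],
      y = layout$y[match(.data$node_a, layout$node)],
      xend = layout$x[match(.data$node_b, layout$node)],
      yend = layout$y[match(.data$node_b, layout$node)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$mean_r)),
      color = "grey50"
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(.data$x, .data$y, size = .data$degree, color = .data$module)
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(.data$x * 1.15, .data$y * 1.15, label = .data$node),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "|mean r|", size = "degree", color = "module")
}

#' Bar plot of ROI beta summaries
#'
#' Mean beta per feature with t-based confidence-interval error bars,
#' social features shaded differently from non-social ones.
#'
#' @param summary_tbl Output of [beta_summary()].
#' @param features Feature tibble for the social flag.
#' @return A ggplot object.
#' @export
plot_beta_summary <- function(summary_tbl, features = default_features()) {
  df <- dplyr::left_join(summary_tbl, features, by = "feature") |>
    dplyr::mutate(feature = factor(.data$feature, levels = features$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$mean_beta,
                                   fill = .data$social)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper), width = 0.3
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey40", `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = "mean beta (95% CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heat map of the between-feature correlation matrix
#'
#' @param corr Correlation matrix from [feature_correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_feature_correlations <- function(corr) {
  df <- tibble::tibble(
    a = factor(rep(rownames(corr), times = ncol(corr)), levels = rownames(corr)),
    b = factor(rep(colnames(corr), each = nrow(corr)), levels = colnames(corr)),
    r = as.vector(corr)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 2) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Inter-rater reliability bar plot
#'
#' @param reliability_tbl Output of [interrater_reliability()].
#' @return A ggplot object.
#' @export
plot_reliability <- function(reliability_tbl) {
  ggplot2::ggplot(reliability_tbl,
                  ggplot2::aes(stats::reorder(.data$feature, .data$r), .data$r)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = mean(reliability_tbl$r), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "inter-rater r (dashed: mean)") +
    ggplot2::theme_minimal()
}
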