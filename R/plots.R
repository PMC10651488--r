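# ggplot2 views of the result types.

#' Volcano plot of a differential-expression table
#' @param object An `fbr_de` table.
#' @param alpha Significance line (unadjusted p), default 0.05.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fbr_de <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$p_value < alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fold_change,
                                   -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("p < %g", alpha)) +
    ggplot2::theme_minimal()
}

#' Convergence of the interface stress under mesh refinement
#' @param object An `fbr_convergence` report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fbr_convergence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$edge_length, .data$max_abs_sx)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "edge length (mm)", y = "max |Sx| (kPa)") +
    ggplot2::theme_minimal()
}

#' Stacked-bar view of a cluster-composition table
#' @param object An `fbr_composition` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fbr_composition <- function(object, ...) {
  by_cols <- setdiff(names(object), grep("^c\\d+$|^pop", names(object),
                                         value = TRUE))
  long <- tidyr::pivot_longer(object, -dplyr::all_of(by_cols),
                              names_to = "cluster", values_to = "fraction")
  long$row <- interaction(long[by_cols], drop = TRUE)
  ggplot2::ggplot(long, ggplot2::aes(.data$row, .data$fraction,
                                     fill = .data$cluster)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of cells") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-cell signature scores by cluster
#' @param scores Tibble from [signature_score()].
#' @param clusters Cluster labels aligned with the score rows.
#' @return A ggplot.
#' @export
plot_signature_scores <- function(scores, clusters) {
  df <- tibble(score = scores$score, cluster = as.factor(clusters))
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$score,
                                   fill = .data$cluster)) +
    ggplot2::geom_violin(scale = "width", show.legend = FALSE) +
    ggplot2::labs(x = "cluster", y = "signature score") +
    ggplot2::theme_minimal()
}

#' Interface stress profile along the load axis
#'
#' Scatter of per-element Sx against the element-centroid x coordinate for
#' tissue elements touching the interface: shows the compressive lobe on the
#' load-facing side and the tensile lobe opposite.
#'
#' @param solution An `fbr_solution` on a mesh with an implant.
#' @return A ggplot.
#' @export
plot_interface_profile <- function(solution) {
  mesh <- solution$problem$mesh
  interface <- mesh$node_sets$interface
  tissue <- mesh$region != "implant"
  touches <- matrix(mesh$elems %in% interface, ncol = 4L)
  sel <- which(tissue & rowSums(touches) > 0L)
  cx <- rowMeans(matrix(mesh$nodes[mesh$elems[sel, ], 1L], ncol = 4L))
  df <- tibble(x = cx, sx_kpa = solution$element_stress[sel, 1L] / 1e3)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$sx_kpa)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "x (mm)", y = "Sx (kPa)") +
    ggplot2::theme_minimal()
}
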