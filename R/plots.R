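#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed against predicted reserve for the three tails
#'
#' @param object A `cpm_cv`.
#' @param ... Unused.
#' @return A ggplot: observed vs out-of-fold predicted CR, one facet per
#'   network-strength tail, with the identity-free least-squares line.
#' @export
autoplot.cpm_cv <- function(object, ...) {
  long <- object$predictions |>
    tidyr::pivot_longer(dplyr::starts_with("predicted_"),
                        names_to = "tail", names_prefix = "predicted_",
                        values_to = "predicted")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted,
                                     y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_wrap(~tail, scales = "free_x") +
    ggplot2::labs(x = "Network-strength predicted CR",
                  y = "Observed CR residual",
                  title = paste0("CPM ", object$scheme, " (p < ",
                                 format(object$threshold), ")")) +
    ggplot2::theme_minimal()
}

#' Plot the threshold-optimisation trace
#'
#' @param object A `cpm_threshold_trace`.
#' @param ... Unused.
#' @return A ggplot of combined-tail out-of-fold r against the
#'   edge-selection threshold (log scale), with the optimum marked.
#' @export
autoplot.cpm_threshold_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$threshold, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Edge-selection p-value threshold",
                  y = "Combined-tail out-of-fold r") +
    ggplot2::theme_minimal()
}

#' Plot residuals against fitted cognition
#'
#' @param object A `cr_residual_model`.
#' @param ... Unused.
#' @return A ggplot of the CR residual distribution.
#' @export
autoplot.cr_residual_model <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$cr_residual)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "CR residual (observed - predicted cognition)",
                  y = "Subjects") +
    ggplot2::theme_minimal()
}

#' Heatmap of a canonical within/between-network edge-count matrix
#'
#' @param mat A 10 x 10 matrix from [canonical_matrix()].
#' @param title Plot title.
#' @return A ggplot tile map; darker cells contain more selected edges.
#' @export
plot_canonical_matrix <- function(mat, title = "Selected edges by network pair") {
  nets <- canonical_networks()
  df <- tibble::as_tibble(as.table(mat), .name_repair = "minimal")
  names(df) <- c("row", "col", "count")
  df$row <- factor(df$row, levels = rev(nets))
  df$col <- factor(df$col, levels = nets)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Edges", title = title) +
    ggplot2::theme_minimal()
}
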