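#' Plot per-stage expression profiles
#'
#' Line plot of per-stage average expression, one line per feature,
#' optionally coloured and facetted by profile call.
#'
#' @param means A [stage_means()]-style tibble (`feature_id` + one column
#'   per stage, in developmental order).
#' @param calls Optional calls tibble (`feature_id`, `call`).
#' @param max_features Thin to at most this many features (default 200).
#' @return A ggplot object.
#' @export
plot_stage_profiles <- function(means, calls = NULL, max_features = 200) {
  stages <- setdiff(names(means), "feature_id")
  long <- tidyr::pivot_longer(means, -"feature_id", names_to = "stage",
                              values_to = "value")
  long$stage <- factor(long$stage, levels = stages)
  if (!is.null(calls)) {
    long <- dplyr::inner_join(
      long, dplyr::select(calls, "feature_id", "call"), by = "feature_id"
    )
  }
  keep <- unique(long$feature_id)
  if (length(keep) > max_features) {
    keep <- keep[seq(1, length(keep), length.out = max_features)]
    long <- dplyr::filter(long, .data$feature_id %in% keep)
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value,
                                          group = .data$feature_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "average expression") +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    p <- p + ggplot2::aes(colour = .data$call) +
      ggplot2::facet_wrap(ggplot2::vars(.data$call))
  }
  p
}

#' Expression heatmap in dendrogram leaf order
#'
#' Tile heatmap of per-stage averages with rows ordered by a
#' [hierarchical_cluster()] result, the display behind the unsupervised
#' three-class figure of array studies.
#'
#' @param means Per-stage averages (`feature_id` + stage columns).
#' @param clusters A [hierarchical_cluster()] tibble for the same features.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(means, clusters) {
  stages <- setdiff(names(means), "feature_id")
  long <- tidyr::pivot_longer(means, -"feature_id", names_to = "stage",
                              values_to = "value")
  long$stage <- factor(long$stage, levels = stages)
  ord <- clusters$feature_id[order(clusters$leaf_position)]
  long$feature_id <- factor(long$feature_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$feature_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black", high = "yellow") +
    ggplot2::labs(x = NULL, y = NULL, fill = "expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Volcano plot of stage-transition tests
#'
#' @param transitions A [transition_tests()] tibble.
#' @param sig_col Significance column to plot (`"q_value"` or `"p_value"`).
#' @param alpha Threshold drawn as a horizontal line.
#' @return A ggplot object, facetted by stage pair.
#' @export
plot_transition_volcano <- function(transitions, sig_col = "q_value",
                                    alpha = 0.05) {
  d <- dplyr::filter(transitions, .data$status == "tested")
  d$pair <- paste(d$earlier, "→", d$later)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_fc,
                                  y = -log10(.data[[sig_col]]))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = "log2 fold change (later - earlier)",
                  y = sprintf("-log10 %s", sig_col)) +
    ggplot2::theme_minimal()
}
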