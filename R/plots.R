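#' @importFrom ggplot2 autoplot ggplot aes geom_bar geom_point geom_segment
#'   geom_hline geom_vline geom_boxplot labs theme_minimal facet_wrap
#'   scale_fill_manual coord_flip position_fill
#' @export
ggplot2::autoplot

.status_palette <- c(
  escape = "#1b9e77", variable_escape = "#d95f02",
  subject = "#7570b3", no_call = "grey70"
)

#' Plot the status composition of call tables
#'
#' Stacked per-dataset bars of the fraction of genes with each XCI
#' status, the standard per-species calling overview.
#'
#' @param object An `xci_calls` tibble (or several row-bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xci_calls
#' @export
autoplot.xci_calls <- function(object, ...) {
  ggplot(object, aes(x = .data$dataset, fill = .data$status)) +
    geom_bar(position = position_fill()) +
    scale_fill_manual(values = .status_palette) +
    labs(x = NULL, y = "fraction of genes", fill = "XCI status") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Female versus male island methylation
#'
#' Scatter of per-island female against male mean methylation with the
#' calling thresholds drawn, the diagnostic view used to justify the
#' 10/15/60% class boundaries.
#'
#' @param island_meths Island x sample means with `sex` (see
#'   [island_methylation()]).
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for
#'   defaults.
#' @return A ggplot.
#' @export
plot_sex_methylation <- function(island_meths, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  sex_means <- sex_mean_comparison(island_meths)
  ggplot(sex_means, aes(x = .data$male_mean, y = .data$female_mean)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_hline(
      yintercept = c(th$meth_escape_max, th$meth_subject_min, th$meth_subject_max),
      linetype = "dashed", colour = "grey40"
    ) +
    geom_vline(xintercept = th$male_meth_cut, linetype = "dotted", colour = "grey40") +
    labs(
      x = "male mean island methylation",
      y = "female mean island methylation"
    ) +
    theme_minimal()
}

#' Plot feature enrichment by XCI status
#'
#' Per-species mean feature values in the escape and subject groups with
#' significance flags, from a tidied enrichment result.
#'
#' @param object An `xci_enrichment` from [test_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xci_enrichment
#' @export
autoplot.xci_enrichment <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(
      c("mean_escape", "mean_subject"),
      names_to = "group", values_to = "mean"
    ) |>
    mutate(group = sub("^mean_", "", .data$group))
  ggplot(long, aes(x = .data$species, y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = long |> filter(.data$significant, .data$group == "escape"),
      aes(label = "*"), vjust = 0, size = 5, show.legend = FALSE
    ) +
    facet_wrap(~feature, scales = "free_y") +
    scale_fill_manual(values = c(escape = "#1b9e77", subject = "#7570b3")) +
    labs(x = NULL, y = "group mean", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the species dendrogram
#'
#' Segment-based rendering of the complete-linkage dendrogram of species
#' XCI call profiles.
#'
#' @param object An `xci_tree` from [cluster_species()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xci_tree
#' @export
autoplot.xci_tree <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  # leaf x-positions in plotting order, then recursive merge coordinates
  leaf_x <- setNames(match(seq_len(n), hc$order), seq_len(n))
  node_x <- numeric(nrow(hc$merge))
  segs <- list()
  for (k in seq_len(nrow(hc$merge))) {
    xs <- vapply(hc$merge[k, ], function(i) {
      if (i < 0) leaf_x[[as.character(-i)]] else node_x[i]
    }, numeric(1))
    ys <- vapply(hc$merge[k, ], function(i) {
      if (i < 0) 0 else hc$height[i]
    }, numeric(1))
    h <- hc$height[k]
    node_x[k] <- mean(xs)
    segs[[k]] <- tibble(
      x = c(xs[1], xs[2], xs[1]), xend = c(xs[1], xs[2], xs[2]),
      y = c(ys[1], ys[2], h), yend = c(h, h, h)
    )
  }
  seg_df <- bind_rows(segs)
  lab_df <- tibble(x = unname(leaf_x), y = 0, label = hc$labels)
  ggplot(seg_df) +
    geom_segment(aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(
      data = lab_df,
      aes(x = .data$x, y = .data$y, label = .data$label),
      angle = 90, hjust = 1.1, size = 3
    ) +
    ggplot2::scale_y_continuous("complete-linkage height") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::expand_limits(y = -0.2 * max(hc$height)) +
    theme_minimal()
}
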