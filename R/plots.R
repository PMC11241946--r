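#' Stacked-bar plot of annotation category proportions
#'
#' Shows, per mark when several are present, the proportion of peak
#' counts and of summed peak length falling in each genomic category —
#' the standard at-a-glance view of where a mark's peaks live.
#'
#' @param annotations [annotate_peaks()] output (one or more marks).
#' @return A ggplot object.
#' @export
plot_annotation_summary <- function(annotations) {
  summ <- map_dfr(unique(annotations$mark), function(mk) {
    summarize_annotation(annotations %>% filter(.data$mark == mk)) %>%
      mutate(mark = mk)
  })
  long <- summ %>%
    tidyr::pivot_longer(c("prop_count", "prop_length"),
                        names_to = "measure", values_to = "proportion") %>%
    mutate(measure = if_else(.data$measure == "prop_count",
                             "peak count", "peak length"),
           category = factor(.data$category, levels = CATEGORY_LEVELS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mark, y = .data$proportion,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "proportion", fill = "category") +
    ggplot2::theme_minimal()
}

#' Boxplot of a category comparison
#'
#' @param object A `regmark_comparison`.
#' @param ... Unused.
#' @return A ggplot object: per-category boxplots of the compared value.
#' @method autoplot regmark_comparison
#' @export
autoplot.regmark_comparison <- function(object, ...) {
  lab <- switch(object$value, log_tpm = "ln(TPM + 1)",
                log_dnds = "ln(dN/dS + 1)", object$value)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$category, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Boxplots of diversity inside vs outside peaks
#'
#' @param object A `peak_overlap_comparison`.
#' @param ... Unused.
#' @return A ggplot object faceted by metric (pi, Dxy).
#' @method autoplot peak_overlap_comparison
#' @export
autoplot.peak_overlap_comparison <- function(object, ...) {
  w <- attr(object, "windows")
  pi_col <- grep("^pi_", names(w), value = TRUE)[1]
  long <- bind_rows(
    tibble(metric = "pi", in_peak = w$in_peak, value = w[[pi_col]]),
    tibble(metric = "dxy", in_peak = w$in_peak, value = w$dxy)
  ) %>%
    mutate(group = if_else(.data$in_peak, "peak (+)", "peak (-)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-site diversity") +
    ggplot2::theme_minimal()
}

#' Heatmap of a sample correlation matrix
#'
#' Tile heatmap of pairwise Spearman correlations with samples ordered by
#' the average-linkage dendrogram, the usual companion of genome-binned
#' coverage clustering.
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(cm) {
  hc <- cluster_samples(cm)
  ord <- hc$labels[hc$order]
  m <- unclass(cm)[ord, ord]
  long <- as_tibble(m, rownames = "sample1") %>%
    tidyr::pivot_longer(-"sample1", names_to = "sample2", values_to = "rho") %>%
    mutate(sample1 = factor(.data$sample1, levels = ord),
           sample2 = factor(.data$sample2, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample1, .data$sample2,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
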