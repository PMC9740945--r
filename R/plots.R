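# ggplot2 views of the result objects.

#' Plot an enrichment result
#'
#' Histogram of the matched-random null overlap fractions with the observed
#' fraction as a vertical line.
#'
#' @param object A `regmap_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regmap_enrichment
#' @export
autoplot.regmap_enrichment <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_fraction,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = "overlap fraction (matched random sets)", y = "replicates",
      title = sprintf("%s: observed %.1f%%, ratio %.1f, p = %.3g",
                      object$track_name, 100 * object$observed_fraction,
                      object$ratio, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot peak scores split by map overlap
#'
#' Box-and-whisker view of track peak scores for peaks overlapped versus not
#' overlapped by the region map (log scale).
#'
#' @param object A `regmap_colocalization` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regmap_colocalization
#' @export
autoplot.regmap_colocalization <- function(object, ...) {
  d <- mutate(object$scores,
              side = if_else(.data$overlapped, "overlapped", "not overlapped"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$side, y = .data$score)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "peak score",
                  subtitle = sprintf("rank-sum p = %.3g (%s)",
                                     object$test$p_two_sided,
                                     object$test$method)) +
    ggplot2::theme_minimal()
}

#' Plot a TSS-distance profile
#'
#' @param object A `regmap_tss_profile` tibble from [tss_distance_profile()].
#' @param ... Unused.
#' @return A ggplot of region-midpoint counts by signed distance to the TSS.
#' @method autoplot regmap_tss_profile
#' @export
autoplot.regmap_tss_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid / 1000,
                                       y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_start[1:2]) / 1000,
                      fill = "steelblue") +
    ggplot2::labs(x = "distance to gene 5' end (kb)",
                  y = "region midpoints") +
    ggplot2::theme_minimal()
}

#' Expression box plots by gene group
#'
#' Draws the P / D1 / D2 expression comparison: FPKM (log scale) per group
#' after the expression cutoff.
#'
#' @param groups Gene-group tibble from [partition_genes()].
#' @param expression Expression tibble (`gene_id`, `fpkm`).
#' @param fpkm_min Expression cutoff (default 0.5 FPKM).
#' @return A ggplot.
#' @export
plot_group_expression <- function(groups, expression, fpkm_min = 0.5) {
  d <- groups %>%
    tidyr::pivot_longer(cols = c("P", "D1", "D2"), names_to = "group_label",
                        values_to = "member") %>%
    filter(.data$member) %>%
    inner_join(expression, by = "gene_id") %>%
    filter(.data$fpkm >= fpkm_min) %>%
    mutate(group_label = factor(.data$group_label, levels = c("P", "D1", "D2")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_label, y = .data$fpkm)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "FPKM") +
    ggplot2::theme_minimal()
}
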