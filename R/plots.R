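#' Heatmap of smoothed copy-number profiles
#'
#' Genome-ordered genes on the x axis, query AOIs on the y axis, smoothed
#' log2 ratio as fill — the usual visual for confirming broad chr7 gain /
#' chr10 loss.
#'
#' @param object A `cnv_profile` from [compute_cnv_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_profile
#' @export
autoplot.cnv_profile <- function(object, ...) {
  df <- tibble::as_tibble(object$smoothed, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "aoi_id",
                        values_to = "log2_ratio") |>
    dplyr::left_join(object$genes[, c("gene_id", "chrom", "genome_order")],
                     by = "gene_id")
  lim <- max(abs(df$log2_ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_order, y = .data$aoi_id,
                                   fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-lim, lim)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "genes (genome order)", y = NULL,
                  fill = "smoothed\nlog2 ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [nb_wald_de()].
#' @param q_cut Significance threshold highlighted (default 0.05 on the
#'   q-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, q_cut = 0.05, ...) {
  tab <- object$table |>
    dplyr::mutate(significant = !is.na(.data$qvalue) & .data$qvalue < q_cut)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$pvalue),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = bquote(log[2] ~ "fold change (" * .(object$levels[2]) *
                               " vs " * .(object$levels[1]) * ")"),
                  y = expression(-log[10] ~ p),
                  colour = paste0("q < ", q_cut)) +
    ggplot2::theme_minimal()
}

#' Signature scores by group
#'
#' Box + jitter plot of tumor-level (or AOI-level) signature scores split
#' by a grouping column joined from the metadata.
#'
#' @param scores Long score tibble (e.g. from [aggregate_by_tumor()]).
#' @param meta Tibble with the unit id column and `group_col`.
#' @param id_col Name of the shared id column (default "tumor_id").
#' @param group_col Grouping column in `meta` (default "arm").
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, meta, id_col = "tumor_id", group_col = "arm") {
  df <- dplyr::left_join(scores, unique(meta[, c(id_col, group_col)]),
                         by = id_col)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[group_col]], y = .data$score,
                                   colour = .data[[group_col]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$signature), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "aggregated Z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Paired positivity plot
#'
#' Tumor-level percent positivity by setting with lines connecting the two
#' tumors of each patient, faceted by arm — the standard display for a
#' paired IHC comparison.
#'
#' @param result A `positivity_result` from [percent_positive()].
#' @param design Tibble with `tumor_id`, `patient_id`, `setting`, `arm`.
#' @return A ggplot object.
#' @export
plot_positivity <- function(result, design) {
  df <- dplyr::inner_join(result$tumor, tibble::as_tibble(design),
                          by = "tumor_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$setting, y = .data$pct_positive)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$setting), size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm)) +
    ggplot2::labs(x = NULL, y = "PD-1 positive cells (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
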