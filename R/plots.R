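# ggplot2 views of the result tables.

#' Expression versus strand dominance ("U") plot
#'
#' Scatter of log(FPKM) against the dominance statistic d for expressed
#' genes; genes dominated by one strand sit at the arms of the U.
#'
#' @param calls An `antisense_calls` tibble with `fpkm` (one sample).
#' @param min_reads Minimum reads per gene to plot (default 20).
#' @return A ggplot object.
#' @export
plot_dominance <- function(calls, min_reads = 20) {
  pts <- dplyr::filter(calls, .data$total >= min_reads, .data$fpkm > 0)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$d, y = log(.data$fpkm))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "d = (sense - antisense) / total reads",
                  y = "log(FPKM)",
                  title = "Expression versus strand dominance") +
    ggplot2::theme_minimal()
}

#' @method autoplot antisense_calls
#' @export
autoplot.antisense_calls <- function(object, ...) plot_dominance(object, ...)

#' Sharing histogram plot
#'
#' Bar chart of how many genes are antisense-called in exactly j samples,
#' faceted by species.
#'
#' @param sharing Output of [sharing_histogram()].
#' @return A ggplot object.
#' @export
plot_sharing <- function(sharing) {
  ggplot2::ggplot(sharing, ggplot2::aes(x = factor(.data$n_shared),
                                        y = .data$n_genes)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species_id), scales = "free_y") +
    ggplot2::labs(x = "number of samples sharing the gene",
                  y = "genes with antisense transcription") +
    ggplot2::theme_minimal()
}

#' Histogram of per-species antisense gene ratios
#'
#' @param summaries Output of [summarize_species()]; only eligible
#'   species/sample cells are drawn.
#' @param bins Number of bins (default 30).
#' @return A ggplot object.
#' @export
plot_antisense_ratios <- function(summaries, bins = 30) {
  el <- dplyr::filter(summaries, .data$eligible,
                      !is.na(.data$ratio_genes_antisense))
  ggplot2::ggplot(el, ggplot2::aes(x = .data$ratio_genes_antisense)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "ratio of genes with antisense transcription",
                  y = "species x sample cells") +
    ggplot2::theme_minimal()
}

#' @method autoplot cog_enrichment
#' @export
autoplot.cog_enrichment <- function(object, test = "fisher", ...) {
  cats <- summarize_categories(object, test = test)
  ggplot2::ggplot(cats, ggplot2::aes(x = stats::reorder(.data$category,
                                                        -.data$n_enriched),
                                     y = .data$n_enriched)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "COG functional category",
                  y = "enriched COG x genome pairs") +
    ggplot2::theme_minimal()
}

#' Strand coverage plot for one gene
#'
#' @param coverage Output of [strand_coverage()].
#' @return A ggplot object.
#' @export
plot_strand_coverage <- function(coverage) {
  long <- tidyr::pivot_longer(coverage, c("sense", "antisense"),
                              names_to = "orientation", values_to = "depth")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$depth,
                                     fill = .data$orientation)) +
    ggplot2::geom_area(alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "position (bp)", y = "read depth") +
    ggplot2::theme_minimal()
}
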