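# ggplot2 views of the three result tables.

#' Plot configuration fractions of an Alu catalog
#'
#' Bar chart of the configuration fractions, one panel per stratum when the
#' summary came from [stratify_by_region()].
#'
#' @param summary Output of [summarize_catalog()] or [stratify_by_region()].
#' @return A ggplot object.
#' @export
plot_catalog <- function(summary) {
  keep <- c("fraction_single", "fraction_dSINE", "fraction_hiSINE",
            "fraction_tiSINE")
  long <- tidyr::pivot_longer(summary, dplyr::all_of(keep),
                              names_to = "configuration", values_to = "fraction")
  long$configuration <- sub("^fraction_", "", long$configuration)
  long$configuration <- factor(long$configuration,
                               levels = c("single", "dSINE", "hiSINE", "tiSINE"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$configuration,
                                          y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "fraction of all Alus") +
    ggplot2::theme_minimal()
  if ("region" %in% names(summary)) p <- p + ggplot2::facet_wrap(~region)
  p
}

#' Plot Aluome enrichment across genome partitions
#'
#' Side-by-side genome and Aluome fractions per partition label, faceted by
#' hierarchy level.
#'
#' @param coverage Output of [aluome_coverage()].
#' @return A ggplot object.
#' @export
plot_aluome <- function(coverage) {
  long <- tidyr::pivot_longer(coverage, c("genome_fraction", "aluome_fraction"),
                              names_to = "set", values_to = "fraction")
  long$set <- sub("_fraction$", "", long$set)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$fraction,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~level, scales = "free_x",
                        labeller = ggplot2::as_labeller(
                          c(`1` = "genomic", `2` = "genic", `3` = "exonic"))) +
    ggplot2::scale_fill_manual(values = c(genome = "grey60", aluome = "firebrick")) +
    ggplot2::labs(x = NULL, y = "fraction of nucleotides", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pooled expression by configuration category
#'
#' Box plots of log10 FPKM per configuration category, the transcript
#' x cell-line pool on display.
#'
#' @param pooled Output of [pool_by_category()].
#' @return A ggplot object.
#' @export
plot_expression <- function(pooled) {
  order <- c("all", "single", "iAlu", "head_head", "tail_tail", "tandem", "noSINE")
  pooled$category <- factor(pooled$category,
                            levels = intersect(order, unique(pooled$category)))
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data$category, y = .data$fpkm)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "FPKM (log scale)") +
    ggplot2::theme_minimal()
}
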