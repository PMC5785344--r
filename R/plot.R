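#' Plot high-bulk allele frequency along the genome
#'
#' Per-chromosome scatter of the donor-allele frequency in the high bulk
#' against physical position (Mbp), with passing candidates highlighted
#' and merged candidate regions shaded. A local replacement for web-based
#' candidate-SNP plotting.
#'
#' @param results association result table ([classify_candidates()]); an
#'   empty candidate set simply renders unhighlighted panels.
#' @param regions optional region table ([cluster_candidates()]).
#' @return A ggplot object (facetted by chromosome).
#' @export
plot_allele_frequency <- function(results, regions = NULL) {
  stopifnot(nrow(results) > 0)
  results$mbp <- results$pos / 1e6
  p <- ggplot2::ggplot(results, ggplot2::aes(x = mbp, y = hab_freq))
  if (!is.null(regions) && nrow(regions) > 0) {
    regions$start_mbp <- regions$start / 1e6
    regions$end_mbp <- regions$end / 1e6
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = start_mbp, xmax = end_mbp),
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3,
      inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = pass), size = 1.2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey55"),
      name = "candidate") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mbp)",
                  y = "Donor-allele frequency (high bulk)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

utils::globalVariables(c("mbp", "hab_freq", "start_mbp", "end_mbp", "pass"))
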