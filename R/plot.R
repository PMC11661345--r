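# ggplot2 views of pipeline results.

#' Locus plot: association panel over gene/PoPS panel
#'
#' Draws the tabular [locus_report()] as a two-panel figure: -log10
#' p-values along the locus colored by LD with the lead variant
#' (credible-set members circled), and gene bodies at their raw meta PoPS
#' score with the genome-wide top-10%/top-1% thresholds as dashed lines.
#'
#' @param run A [run_pipeline()] result.
#' @param signal_index Which isolated signal to draw.
#' @param panel The mixed `ld_panel` used in the run.
#' @return A ggplot object.
#' @export
plot_locus <- function(run, signal_index, panel) {
  rep <- locus_report(run, signal_index, panel)
  v <- dplyr::mutate(rep$variants, panel = "association",
                     y = -log10(pmax(.data$p, 1e-300)))
  g <- dplyr::mutate(rep$genes, panel = "PoPS",
                     mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = v,
                        ggplot2::aes(x = .data$pos, y = .data$y,
                                     colour = .data$r2_lead,
                                     shape = .data$in_cs)) +
    ggplot2::geom_hline(data = tibble::tibble(panel = "association",
                                              yint = -log10(5e-8)),
                        ggplot2::aes(yintercept = .data$yint),
                        linetype = "dashed") +
    ggplot2::geom_segment(data = g,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$meta_score,
                                       yend = .data$meta_score),
                          linewidth = 2, colour = "steelblue") +
    ggplot2::geom_text(data = g,
                       ggplot2::aes(x = .data$mid, y = .data$meta_score,
                                    label = .data$gene),
                       vjust = -0.8, size = 2.6) +
    ggplot2::geom_hline(data = tibble::tibble(
      panel = "PoPS", yint = c(rep$pops_top10_threshold,
                               rep$pops_top1_threshold)),
      ggplot2::aes(yintercept = .data$yint),
      linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_colour_viridis_c(name = expression(r^2), limits = c(0, 1)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 19, `FALSE` = 1),
                                name = "in credible set") +
    ggplot2::labs(x = sprintf("chr%s position (bp)",
                              run$loci[[signal_index]]$chrom),
                  y = NULL)
}

#' @rdname loco_ridge
#' @method autoplot pops_fit
#' @export
autoplot.pops_fit <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "raw PoPS score", y = "genes",
                  title = if (is.na(object$ancestry)) "PoPS scores"
                          else sprintf("PoPS scores (%s)", object$ancestry))
}

#' Evidence heat-strip for prioritized genes
#'
#' Percentile-style overview of the evidence table: one row per prioritized
#' gene, columns for distance (kb), PoPS percentile and meta gene z.
#'
#' @param run A [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_evidence <- function(run) {
  ev <- run$evidence
  if (nrow(ev) == 0) abort("no prioritized genes to plot")
  long <- ev |>
    dplyr::transmute(gene = .data$gene,
                     `distance (kb)` = .data$distance_kb,
                     `PoPS percentile` = .data$pops_percentile,
                     `MAGMA meta z` = .data$magma_meta_z) |>
    tidyr::pivot_longer(-"gene", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$gene,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)), size = 2.8) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}
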