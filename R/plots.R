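#' Manhattan-style plot of combined gene associations
#'
#' One point per gene at its transcription start, height
#' `-log10(p_combined)`; the dashed line marks the Bonferroni threshold
#' when one is attached.
#'
#' @param object A `twas_combined` tibble (after [select_significant()]
#'   the significant genes are coloured).
#' @param gene_meta Tibble with gene_id, chrom, tss for positions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twas_combined <- function(object, gene_meta, ...) {
  idx <- match(object$gene, gene_meta$gene_id)
  df <- dplyr::mutate(as_tibble(object),
                      pos = gene_meta$tss[idx] / 1e6,
                      chrom = gene_meta$chrom[idx],
                      neglogp = -log10(.data$p_combined))
  sig <- if ("significant" %in% names(df)) df$significant else FALSE
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$neglogp)) +
    ggplot2::geom_point(ggplot2::aes(colour = sig), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10] * "(combined P)")) +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold")
  if (!is.null(thr) && is.finite(thr))
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed", colour = "firebrick")
  p
}

#' Posterior inclusion probability plot
#'
#' Lollipop plot of per-gene PIPs by region; credible-set members are
#' filled.
#'
#' @param object A `twas_finemap` tibble from [finemap_tissue()] or
#'   [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twas_finemap <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$pip)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$gene, y = 0,
                                       yend = .data$pip), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$in_credible_set),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "firebrick"),
                               name = "90% credible set") +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "posterior inclusion probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
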