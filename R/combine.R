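#' Cauchy combination of per-tissue P values
#'
#' Transforms each P value to a standard Cauchy quantile
#' `tan((0.5 - p) * pi)` and averages; under the null the average is again
#' standard Cauchy, so `p_combined = 1/2 - atan(T) / pi`. For numerical
#' stability the quantile is replaced by `1 / (p * pi)` when `p < 1e-15`
#' (the two agree to first order there), P values are clipped to
#' `1 - 1e-16` at the upper end, and the combined P is floored at
#' `1e-300`. The analytic tail is highly accurate precisely when the
#' combined P is small.
#'
#' @param tissue_ps Numeric vector of P values in (0, 1].
#' @return List: `t_stat` (the average Cauchy quantile), `p_combined`.
#' @export
cauchy_combine <- function(tissue_ps) {
  if (length(tissue_ps) < 1L)
    abort("need at least one tissue P value", class = "crosstwas_data_error")
  if (any(!is.finite(tissue_ps)) || any(tissue_ps <= 0) ||
      any(tissue_ps > 1))
    abort("P values must lie in (0, 1]", class = "crosstwas_data_error")
  p <- pmin(tissue_ps, 1 - 1e-16)
  # tan((0.5 - p) * pi) evaluated through the cotangent identity, which
  # avoids the cancellation in 0.5 - p for small p; below 1e-15 the
  # first-order form 1/(p * pi) is exact to machine precision
  q <- ifelse(p < 1e-15, 1 / (p * pi),
              ifelse(p <= 0.5, 1 / tan(p * pi), -1 / tan((1 - p) * pi)))
  t_stat <- mean(q)
  # atan(1/T)/pi is the same tail without cancellation when T is large
  p_comb <- if (t_stat > 1) atan(1 / t_stat) / pi else
    0.5 - atan(t_stat) / pi
  list(t_stat = t_stat, p_combined = max(p_comb, 1e-300))
}

#' Combine per-tissue TWAS P values per gene
#'
#' Equal-weight Cauchy combination across the tissues in which a gene has a
#' retained model; the number of combined tissues therefore varies by gene.
#'
#' @param assoc A `twas_association` tibble (gene, tissue, p, ...).
#' @return Tibble (class `twas_combined`): gene, n_tissues, tissue_ps
#'   (list-column), t_stat, p_combined.
#' @export
combine_tissues <- function(assoc) {
  out <- assoc |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_tissues = dplyr::n(),
                     tissue_ps = list(.data$p), .groups = "drop")
  cc <- purrr::map(out$tissue_ps, cauchy_combine)
  out$t_stat <- purrr::map_dbl(cc, "t_stat")
  out$p_combined <- purrr::map_dbl(cc, "p_combined")
  class(out) <- c("twas_combined", class(out))
  out
}

#' Bonferroni selection of significant genes
#'
#' Threshold `alpha / m` with `m` the number of genes tested; significance
#' is the strict inequality `p < alpha / m`.
#'
#' @param p_values Named or unnamed numeric vector of combined P values.
#' @param alpha Family-wise error rate.
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return List: `threshold`, `significant` (logical vector aligned to
#'   `p_values`), `m`.
#' @export
bonferroni_select <- function(p_values, alpha = 0.05,
                              m = length(p_values)) {
  if (m < 1L) abort("number of tests m must be >= 1",
                    class = "crosstwas_data_error")
  thr <- alpha / m
  list(threshold = thr, significant = p_values < thr, m = m)
}

#' Default LD-extensive exclusion regions
#'
#' The extended MHC (chr6:25,000,000-34,000,000), the canonical
#' LD-extensive region whose TWAS hits are conventionally excluded.
#' Intervals are half-open: `[start, end)`, 1-based start.
#'
#' @return Tibble: chrom, start, end, label.
#' @export
default_region_blacklist <- function() {
  tibble(chrom = "6", start = 25e6, end = 34e6, label = "extended MHC")
}

#' Flag genes in LD-extensive exclusion regions
#'
#' A gene is flagged when its interval overlaps a blacklist interval under
#' the half-open convention (`[start, end)`, 1-based start): a gene ending
#' exactly at a region's start, or starting exactly at its end, is not
#' flagged. Flagged genes are reported but removed from final significant
#' lists.
#'
#' @param genes Tibble: gene_id, chrom, start (or tss), end (or tes).
#' @param blacklist Tibble: chrom, start, end; default
#'   [default_region_blacklist()].
#' @return Logical vector aligned to `genes` rows.
#' @export
flag_excluded_regions <- function(genes, blacklist = default_region_blacklist()) {
  if (!all(c("chrom", "start", "end") %in% names(blacklist)) ||
      (nrow(blacklist) > 0 && any(blacklist$end <= blacklist$start)))
    abort("malformed region blacklist (need chrom, start < end)",
          class = "crosstwas_config_error")
  gs <- genes$start %||% genes$tss
  ge <- genes$end %||% genes$tes
  flag <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(blacklist))) {
    b <- blacklist[i, ]
    # region half-open [start, end); a gene ending exactly at `start`
    # (or starting exactly at `end`) does not overlap
    flag <- flag | (genes$chrom == b$chrom & gs < b$end & ge > b$start)
  }
  flag
}

#' Select significant genes after multiple-testing and region filters
#'
#' Applies [bonferroni_select()] to the combined P values and
#' [flag_excluded_regions()] to the gene coordinates; the final
#' significant set excludes flagged genes.
#'
#' @param combined A `twas_combined` tibble.
#' @param gene_meta Tibble with gene_id, chrom, tss, tes (panel
#'   `gene_meta` works).
#' @param alpha Family-wise error rate.
#' @param m Number of tests (defaults to the number of combined genes).
#' @param blacklist Region blacklist tibble.
#' @return The input with `significant` and `excluded_region` columns;
#'   attribute `"threshold"` holds `alpha / m`.
#' @export
select_significant <- function(combined, gene_meta, alpha = 0.05,
                               m = nrow(combined),
                               blacklist = default_region_blacklist()) {
  sel <- bonferroni_select(combined$p_combined, alpha = alpha, m = m)
  idx <- match(combined$gene, gene_meta$gene_id)
  gm <- tibble(gene_id = combined$gene,
               chrom = gene_meta$chrom[idx],
               start = gene_meta$tss[idx], end = gene_meta$tes[idx])
  excl <- flag_excluded_regions(gm, blacklist)
  out <- dplyr::mutate(combined,
                       excluded_region = excl,
                       significant = sel$significant & !excl)
  attr(out, "threshold") <- sel$threshold
  out
}
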