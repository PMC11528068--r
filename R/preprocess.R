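#' Filter lowly expressed genes and align the paired matrices
#'
#' Removes genes expressed (value strictly greater than zero) in fewer than
#' `cell_frac` of cells or fewer than `spot_frac` of spots, then restricts
#' both matrices to the intersection of surviving genes, in identical order.
#' Filtering is evaluated on the raw input values; no normalization or log
#' transform is imposed.
#'
#' @param sc a [gene_expression_matrix()].
#' @param st a [spatial_dataset()].
#' @param cell_frac,spot_frac prevalence thresholds in (0, 1); a gene at
#'   exactly the threshold survives (the removal condition is "fewer than").
#' @return list with filtered, gene-aligned `sc` and `st`.
#' @export
filter_and_align <- function(sc, st, cell_frac = 0.05, spot_frac = 0.01) {
  stopifnot(inherits(sc, "GeneExpressionMatrix"), inherits(st, "SpatialDataset"))
  if (cell_frac <= 0 || cell_frac >= 1 || spot_frac <= 0 || spot_frac >= 1)
    stop_sf("fractions must lie in (0, 1)")
  n1 <- nrow(sc$values); n2 <- nrow(st$values)
  common <- intersect(sc$gene_ids, st$gene_ids)
  prev_sc <- colSums(sc$values[, common, drop = FALSE] > 0) / n1
  prev_st <- colSums(st$values[, common, drop = FALSE] > 0) / n2
  keep <- common[prev_sc >= cell_frac & prev_st >= spot_frac]
  if (!length(keep))
    stop_sf("no genes survive filtering; relax cell_frac/spot_frac")
  sc2 <- gene_expression_matrix(sc$values[, keep, drop = FALSE],
                                labels = sc$labels)
  st2 <- spatial_dataset(st$values[, keep, drop = FALSE], coords = st$coords)
  list(sc = sc2, st = st2)
}
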