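# Colocalization of cell-type attribution maps (ICC) and hypergeometric
# enrichment of ligand/receptor expression in high-attribution regions.

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    flag_note("zero vector in cosine similarity; returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Integrated correlation coefficient matrix of attribution maps
#'
#' For every pair of cell-type attribution maps, flattens the grids (spot
#' pixels only by default, so the constant background cannot inflate the
#' correlations) and averages three components: Gaussian mutual information
#' (same closed form and clamp as [mutual_information()]), cosine
#' similarity, and Pearson correlation. The diagonal is finite because of
#' the MI clamp.
#'
#' @param maps named list of `CellTypeAttribution`s on a common raster.
#' @param map optional [build_pixel_map()]; when supplied only spot-bearing
#'   pixels enter the flattened vectors, otherwise the full grid is used.
#' @return `ICCMatrix`: list with symmetric `icc` plus component matrices
#'   `mi`, `sc`, `pcc` (each `q x q`) and the vector length `T`.
#' @export
icc_matrix <- function(maps, map = NULL) {
  if (length(maps) < 2) stop_sf("need at least 2 attribution maps")
  vecs <- lapply(maps, function(m) {
    v <- m$values
    if (!is.null(map)) {
      px <- spot_pixels(map)
      v <- v[cbind(px$row + 1L, px$col + 1L)]
    }
    as.numeric(v)
  })
  q <- length(vecs)
  nm <- names(maps) %||% paste0("type", seq_len(q))
  mi <- sc <- pcc <- matrix(0, q, q, dimnames = list(nm, nm))
  for (i in seq_len(q)) for (j in i:q) {
    a <- vecs[[i]]; b <- vecs[[j]]
    mi[i, j] <- mi[j, i] <- mutual_information(a, b)
    sc[i, j] <- sc[j, i] <- cosine_sim(a, b)
    pcc[i, j] <- pcc[j, i] <- pearson_cor(a, b)
  }
  structure(list(icc = (mi + sc + pcc) / 3, mi = mi, sc = sc, pcc = pcc,
                 T = length(vecs[[1]])),
            class = "ICCMatrix")
}

#' Difference of two ICC matrices between conditions
#'
#' @param icc1,icc2 `ICCMatrix` objects over the same cell types.
#' @return matrix `ICC(cond2) - ICC(cond1)`.
#' @export
icc_delta <- function(icc1, icc2) {
  stopifnot(inherits(icc1, "ICCMatrix"), inherits(icc2, "ICCMatrix"))
  icc2$icc - icc1$icc
}

#' Upper-tail hypergeometric probability for spot-set overlap
#'
#' Probability of observing at least `C` common spots between a random
#' `H`-subset and a fixed `N`-subset of `M` background spots, evaluated with
#' exact log-binomial arithmetic. `C = 0` returns exactly 1.
#'
#' @param M background spot count.
#' @param N ligand/receptor-expressed spot count (`N <= M`).
#' @param H high-attribution spot count (`H <= M`).
#' @param C overlap count (`0 <= C <= min(H, N)`).
#' @return p-value in (0, 1].
#' @export
hypergeometric_p <- function(M, N, H, C) {
  if (any(c(M, N, H, C) < 0) || N > M || H > M || C > min(H, N))
    stop_sf("inconsistent counts: need 0 <= C <= min(H, N) and N, H <= M")
  if (C == 0) return(1)
  k <- C:min(H, N)
  lp <- lchoose(N, k) + lchoose(M - N, H - k) - lchoose(M, H)
  min(sum(exp(lp)), 1)
}

#' Hypergeometric enrichment of a gene in high-attribution spots
#'
#' Tests whether the spots expressing `gene` (value strictly positive) are
#' enriched among the top-`top_frac` attribution spots of one cell type's
#' attribution map, against the background of all tissue spots.
#'
#' @param att a `CellTypeAttribution`.
#' @param st a [spatial_dataset()].
#' @param gene gene id present in `st`.
#' @param map the [build_pixel_map()] shared by the maps.
#' @param top_frac high-attribution fraction (default top 20%).
#' @return `EnrichmentTest`: list with counts `M`, `N`, `H`, `C`, `p_value`
#'   and logical `significant` (`p < 0.05`).
#' @export
attribution_enrichment <- function(att, st, gene, map, top_frac = 0.2) {
  stopifnot(inherits(st, "SpatialDataset"))
  if (!gene %in% st$gene_ids) stop_sf("gene absent from spatial data: ", gene)
  M_spots <- st$spot_ids
  N_spots <- M_spots[st$values[, gene] > 0]
  H_spots <- intersect(high_attribution_spots(att, map, top_frac), M_spots)
  C_spots <- intersect(N_spots, H_spots)
  p <- hypergeometric_p(length(M_spots), length(N_spots), length(H_spots),
                        length(C_spots))
  structure(list(gene = gene, M = length(M_spots), N = length(N_spots),
                 H = length(H_spots), C = length(C_spots), p_value = p,
                 significant = p < 0.05),
            class = "EnrichmentTest")
}
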