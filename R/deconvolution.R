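# Reference-based deconvolution from the fused correlation tensor, plus the
# adjusted Rand index for spatial-domain agreement.

#' Fuse the correlation tensor into per-type spot profiles
#'
#' Each metric layer is min-max normalized to `[0, 1]` over all entries
#' (`fuse = "minmax"`, the default; `"raw"` averages the layers on their
#' native scales), the three layers are averaged per (cell, spot), and cell
#' rows are averaged within each cell type, giving one comprehensive
#' correlation profile per type over the spots.
#'
#' @param tensor a [build_tensor()] result.
#' @param labels cell type per cell (named by cell id, or in tensor order).
#' @param fuse `"minmax"` or `"raw"`.
#' @return matrix `q types x n2 spots` of fused profiles.
#' @export
fuse_and_profile <- function(tensor, labels, fuse = c("minmax", "raw")) {
  stopifnot(inherits(tensor, "CorrelationTensor"))
  fuse <- match.arg(fuse)
  if (!is.null(names(labels))) labels <- labels[tensor$cell_ids]
  labels <- as.character(labels)
  if (length(labels) != length(tensor$cell_ids) || anyNA(labels))
    stop_sf("every cell needs a type label")
  wbar <- 0
  for (i in 1:3) {
    layer <- tensor$values[i, , , drop = FALSE]
    dim(layer) <- dim(tensor$values)[2:3]
    if (fuse == "minmax") {
      lo <- min(layer); hi <- max(layer)
      layer <- if (hi > lo) (layer - lo) / (hi - lo) else layer * 0
    }
    wbar <- wbar + layer / 3
  }
  types <- sort(unique(labels))
  prof <- matrix(0, length(types), ncol(wbar),
                 dimnames = list(types, tensor$spot_ids))
  for (t in types) {
    rows <- which(labels == t)
    if (!length(rows)) stop_sf("empty cell type: ", t)
    prof[t, ] <- colMeans(wbar[rows, , drop = FALSE])
  }
  prof
}

#' Per-spot cell-type proportions from fused profiles
#'
#' Normalizes each spot's per-type comprehensive correlation values to the
#' simplex: negative entries are clipped to 0, then each spot row is divided
#' by its sum. All-zero rows fall back to the uniform distribution (with a
#' warning). The predominant type per spot is the argmax, ties broken by the
#' lexicographically first type.
#'
#' @param profiles matrix `q x n2` from [fuse_and_profile()].
#' @return `ProportionMatrix`: list with `values` (`n2 x q`, rows on the
#'   simplex), `type_names`, `spot_ids`, `predominant` (character per spot).
#' @export
spot_proportions <- function(profiles) {
  p <- t(pmax(profiles, 0))
  rs <- rowSums(p)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " spot(s) with all-zero profiles set to uniform")
    p[zero, ] <- 1 / ncol(p)
    rs[zero] <- 1
  }
  p <- p / rs
  types <- rownames(profiles)
  pred <- types[apply(p, 1, which.max)]     # which.max = first (lexicographic)
  structure(list(values = p, type_names = types,
                 spot_ids = rownames(p), predominant = pred),
            class = "ProportionMatrix")
}

#' Deconvolve per-spot cell-type proportions
#'
#' Convenience wrapper: [fuse_and_profile()] then [spot_proportions()].
#'
#' @inheritParams fuse_and_profile
#' @return a `ProportionMatrix`.
#' @export
deconvolve <- function(tensor, labels, fuse = c("minmax", "raw")) {
  fuse <- match.arg(fuse)
  p <- spot_proportions(fuse_and_profile(tensor, labels, fuse))
  p$provenance <- list(fusion = fuse, rho2_clamp = tensor$rho2_clamp,
                       n_cells = length(tensor$cell_ids))
  p
}

#' Adjusted Rand index between two spot partitions
#'
#' Chance-corrected agreement between a clustering (e.g. predominant cell
#' type per spot) and a reference region labeling, from the contingency
#' table with exact binomial coefficients. Ranges over `[-1, 1]`; the
#' degenerate case of a single cluster on both sides is defined as 1.
#'
#' @param clusters,regions vectors of equal length labeling the same spots.
#' @return scalar in \[-1, 1\].
#' @export
ari <- function(clusters, regions) {
  if (!length(clusters)) stop_sf("empty input")
  if (length(clusters) != length(regions)) stop_sf("length mismatch")
  n <- length(clusters)
  tab <- table(clusters, regions)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  exp_idx <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  if (max_idx == exp_idx) return(1)       # both sides a single cluster
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
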