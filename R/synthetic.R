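# Synthetic paired-data generator: negative-binomial single cells with
# disjoint type signatures, spatially clustered placement, and square-grid
# pseudo-spots whose expression is the sum of their member cells — the same
# construction used to benchmark deconvolution on single-cell-resolution
# spatial data (a 14x14 grid over ~1500 cells, half held out as the
# reference, yields on the order of 189 occupied spots with 1-18 cells).

#' Configuration of the synthetic paired dataset
#'
#' @param q number of cell types (>= 2).
#' @param m number of genes.
#' @param signature_genes_per_type genes elevated in exactly one type;
#'   signature sets are disjoint (`q * signature_genes_per_type <= m`).
#' @param n_cells total simulated cells (before the reference split).
#' @param grid `(rows, cols)` of square pseudo-spot tiles.
#' @param cells_per_spot_range admissible per-spot occupancy (reported, and
#'   asserted by the generator tests).
#' @param sig_mean,bg_mean negative-binomial means of signature genes in
#'   their own type vs all other genes (fold change `sig_mean / bg_mean`).
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`).
#' @param noise sd of the per-cell log-normal library-size factor.
#' @param mix_frac fraction of cells placed uniformly rather than in their
#'   type's spatial blob.
#' @param blob_sd standard deviation of the per-type Gaussian blobs.
#' @param domain width/height of the square tissue domain.
#' @param reference_frac fraction of cells held out as the single-cell
#'   reference (the rest are gridded into pseudo-spots).
#' @param seed integer seed.
#' @return `SyntheticConfig` list.
#' @export
synthetic_config <- function(q = 4L, m = 100L, signature_genes_per_type = 8L,
                             n_cells = 1500L, grid = c(14L, 14L),
                             cells_per_spot_range = c(1L, 18L),
                             sig_mean = 20, bg_mean = 1, dispersion = 0.5,
                             noise = 0.1, mix_frac = 0.5, blob_sd = 18,
                             domain = c(100, 100), reference_frac = 0.5,
                             seed = 0L) {
  stopifnot(q >= 2, m >= 3, q * signature_genes_per_type <= m,
            n_cells >= q * 2, length(grid) == 2, all(grid >= 1),
            cells_per_spot_range[1] >= 1, dispersion > 0, sig_mean > bg_mean,
            bg_mean > 0, reference_frac > 0, reference_frac < 1)
  structure(list(q = as.integer(q), m = as.integer(m),
                 signature_genes_per_type = as.integer(signature_genes_per_type),
                 n_cells = as.integer(n_cells), grid = as.integer(grid),
                 cells_per_spot_range = as.integer(cells_per_spot_range),
                 sig_mean = sig_mean, bg_mean = bg_mean,
                 dispersion = dispersion, noise = noise, mix_frac = mix_frac,
                 blob_sd = blob_sd, domain = domain,
                 reference_frac = reference_frac, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

type_signatures <- function(cfg) {
  g <- cfg$signature_genes_per_type
  lapply(seq_len(cfg$q), function(t) paste0("gene", ((t - 1) * g + 1):(t * g)))
}

# Blob centers spread on a circle inside the domain.
type_centers <- function(cfg) {
  ang <- 2 * pi * (seq_len(cfg$q) - 1) / cfg$q
  cbind(cfg$domain[1] / 2 + 0.3 * cfg$domain[1] * cos(ang),
        cfg$domain[2] / 2 + 0.3 * cfg$domain[2] * sin(ang))
}

#' Simulate labeled single cells with spatial coordinates
#'
#' Counts are negative binomial with elevated means on the cell's type
#' signature genes and a per-cell log-normal size factor (sd `noise`).
#' Cells sit in one Gaussian blob per type, with a `mix_frac` fraction
#' placed uniformly over the domain.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `expr` (a [gene_expression_matrix()] of all cells,
#'   labels = cell type) and `coords` (data.frame `cell_id`, `x`, `y`).
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_cells
    genes <- paste0("gene", seq_len(cfg$m))
    cells <- paste0("cell", seq_len(n))
    types <- paste0("type", rep_len(seq_len(cfg$q), n))
    sig <- type_signatures(cfg)
    centers <- type_centers(cfg)
    mu <- matrix(cfg$bg_mean, n, cfg$m, dimnames = list(cells, genes))
    for (t in seq_len(cfg$q))
      mu[types == paste0("type", t), sig[[t]]] <- cfg$sig_mean
    size_factor <- exp(rnorm(n, 0, cfg$noise))
    counts <- matrix(rnbinom(n * cfg$m, mu = mu * size_factor,
                             size = 1 / cfg$dispersion),
                     n, cfg$m, dimnames = list(cells, genes))
    uniform <- runif(n) < cfg$mix_frac
    x <- ifelse(uniform, runif(n, 0, cfg$domain[1]),
                clamp(rnorm(n, centers[match(types, paste0("type", seq_len(cfg$q))), 1],
                            cfg$blob_sd), 0, cfg$domain[1]))
    y <- ifelse(uniform, runif(n, 0, cfg$domain[2]),
                clamp(rnorm(n, centers[match(types, paste0("type", seq_len(cfg$q))), 2],
                            cfg$blob_sd), 0, cfg$domain[2]))
    labels <- data.frame(cell_type = types, row.names = cells)
    list(expr = gene_expression_matrix(counts, labels = labels),
         coords = data.frame(cell_id = cells, x = x, y = y))
  })
}

#' Grid single cells into square pseudo-spots
#'
#' Tiles the bounding box of the cell coordinates into `grid[1] x grid[2]`
#' squares, sums the member cells' expression per tile into one spot vector,
#' uses the tile center as the spot coordinate, drops empty tiles, and
#' records the ground-truth composition (member type counts / member count).
#'
#' @param cells a [gene_expression_matrix()] with a `cell_type` label.
#' @param coords data.frame `cell_id`, `x`, `y` for those cells.
#' @param grid integer `(rows, cols)`.
#' @return list with `st` (a [spatial_dataset()]) and `truth` (list with
#'   simplex `values` matrix spots x types, and `members` per spot).
#' @export
grid_to_spots <- function(cells, coords, grid = c(14L, 14L)) {
  stopifnot(inherits(cells, "GeneExpressionMatrix"))
  coords <- as.data.frame(coords)
  ord <- match(cells$cell_ids, coords$cell_id)
  if (anyNA(ord)) stop_sf("coords missing some cells")
  x <- coords$x[ord]; y <- coords$y[ord]
  rows <- grid[1]; cols <- grid[2]
  xr <- range(x); yr <- range(y)
  wx <- diff(xr) / cols; wy <- diff(yr) / rows
  tx <- if (wx > 0) pmin(cols - 1, floor((x - xr[1]) / wx)) else rep(0, length(x))
  ty <- if (wy > 0) pmin(rows - 1, floor((y - yr[1]) / wy)) else rep(0, length(y))
  tile <- ty * cols + tx
  occupied <- sort(unique(tile))
  if (!length(occupied)) stop_sf("all tiles empty")
  types <- sort(unique(cells$labels$cell_type))
  spot_ids <- paste0("spot", occupied)
  vals <- matrix(0, length(occupied), ncol(cells$values),
                 dimnames = list(spot_ids, cells$gene_ids))
  truth <- matrix(0, length(occupied), length(types),
                  dimnames = list(spot_ids, types))
  members <- vector("list", length(occupied))
  cx <- cy <- numeric(length(occupied))
  for (i in seq_along(occupied)) {
    sel <- tile == occupied[i]
    vals[i, ] <- colSums(cells$values[sel, , drop = FALSE])
    tt <- table(factor(cells$labels$cell_type[sel], levels = types))
    truth[i, ] <- as.numeric(tt) / sum(tt)
    members[[i]] <- cells$cell_ids[sel]
    tj <- occupied[i] %% cols; ti <- occupied[i] %/% cols
    cx[i] <- xr[1] + (tj + 0.5) * wx
    cy[i] <- yr[1] + (ti + 0.5) * wy
  }
  st <- spatial_dataset(vals, coords = data.frame(spot_id = spot_ids,
                                                  x = cx, y = cy))
  list(st = st,
       truth = list(values = truth, members = members,
                    occupancy = lengths(members)))
}

#' Simulate a paired single-cell + spatial fixture with known truth
#'
#' Simulates cells, holds out a uniform random `reference_frac` of them as
#' the single-cell reference, grids the remainder into pseudo-spots, and
#' returns the paired dataset together with the ground-truth per-spot
#' composition.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `sc` (reference [gene_expression_matrix()]), `st`
#'   ([spatial_dataset()] of pseudo-spots), `truth`, `cells` (all simulated
#'   cells and coordinates), and `cfg`.
#' @export
simulate_paired <- function(cfg = synthetic_config()) {
  sim <- simulate_cells(cfg)
  ref_ids <- withr::with_seed(cfg$seed + 1L, {
    ids <- sim$expr$cell_ids
    sample(ids, round(cfg$reference_frac * length(ids)))
  })
  spot_ids <- setdiff(sim$expr$cell_ids, ref_ids)
  subset_gem <- function(ids)
    gene_expression_matrix(sim$expr$values[ids, , drop = FALSE],
                           labels = sim$expr$labels[ids, , drop = FALSE])
  sc <- subset_gem(ref_ids)
  gs <- grid_to_spots(subset_gem(spot_ids),
                      sim$coords[sim$coords$cell_id %in% spot_ids, ],
                      cfg$grid)
  list(sc = sc, st = gs$st, truth = gs$truth, cells = sim, cfg = cfg)
}
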