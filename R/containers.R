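#' Construct a labeled single-cell expression matrix
#'
#' The reference side of a paired dataset: a nonnegative cells x genes matrix
#' with per-cell label annotations (cell type, optionally a second label such
#' as developmental stage).
#'
#' @param values numeric matrix, cells in rows, genes in columns; finite and
#'   nonnegative.
#' @param gene_ids,cell_ids character identifiers; taken from dimnames when
#'   omitted. Duplicates are rejected.
#' @param labels data.frame with one row per cell (rownames = cell ids) and
#'   one or two label columns, the first being the cell type.
#' @return An object of class `GeneExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `labels`.
#' @export
gene_expression_matrix <- function(values, gene_ids = colnames(values),
                                   cell_ids = rownames(values), labels) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop_sf("gene_ids and cell_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stop_sf("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop_sf("duplicate cell ids")
  if (length(gene_ids) != ncol(values) || length(cell_ids) != nrow(values))
    stop_sf("id lengths do not match matrix dimensions")
  if (!all(is.finite(values))) stop_sf("expression values must be finite")
  if (any(values < 0)) stop_sf("expression values must be nonnegative")
  labels <- as.data.frame(labels)
  missing <- setdiff(cell_ids, rownames(labels))
  if (length(missing))
    stop_sf("cells missing from labels: ", paste(missing, collapse = ", "))
  labels <- labels[cell_ids, , drop = FALSE]
  if (anyNA(labels)) stop_sf("every cell needs a value for each label column")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 labels = labels),
            class = "GeneExpressionMatrix")
}

#' Construct a spatial expression dataset
#'
#' A nonnegative spots x genes matrix together with one 2-D coordinate per
#' spot (arbitrary units).
#'
#' @param values numeric matrix, spots in rows, genes in columns.
#' @param gene_ids,spot_ids character identifiers; taken from dimnames when
#'   omitted.
#' @param coords data.frame with columns `spot_id`, `x`, `y` covering every
#'   spot exactly once.
#' @return An object of class `SpatialDataset`.
#' @export
spatial_dataset <- function(values, gene_ids = colnames(values),
                            spot_ids = rownames(values), coords) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(spot_ids))
    stop_sf("gene_ids and spot_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (anyDuplicated(gene_ids)) stop_sf("duplicate gene ids")
  if (anyDuplicated(spot_ids)) stop_sf("duplicate spot ids")
  if (length(gene_ids) != ncol(values) || length(spot_ids) != nrow(values))
    stop_sf("id lengths do not match matrix dimensions")
  if (!all(is.finite(values))) stop_sf("expression values must be finite")
  if (any(values < 0)) stop_sf("expression values must be nonnegative")
  coords <- as.data.frame(coords)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(coords)))
    stop_sf("coords needs columns spot_id, x, y")
  coords$spot_id <- as.character(coords$spot_id)
  if (anyDuplicated(coords$spot_id)) stop_sf("duplicate spot ids in coords")
  missing <- setdiff(spot_ids, coords$spot_id)
  if (length(missing))
    stop_sf("spots missing from coords: ", paste(missing, collapse = ", "))
  coords <- coords[match(spot_ids, coords$spot_id), need]
  rownames(coords) <- NULL
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y)))
    stop_sf("spot coordinates must be finite")
  dimnames(values) <- list(spot_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, spot_ids = spot_ids,
                 coords = coords),
            class = "SpatialDataset")
}

#' @export
print.GeneExpressionMatrix <- function(x, ...) {
  cat(sprintf("GeneExpressionMatrix: %d cells x %d genes; labels: %s\n",
              nrow(x$values), ncol(x$values),
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat(sprintf("SpatialDataset: %d spots x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.GeneExpressionMatrix <- function(x) dim(x$values)

#' @export
dim.SpatialDataset <- function(x) dim(x$values)
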