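# Rasterization of spot coordinates and per-cell pseudo-image rendering.
# Convention: origin top-left, row-major, y axis flipped (max y -> row 0);
# row/col indices stored zero-based.

# Infer a raster dimension from one coordinate axis: if the unique values are
# (close to) equally spaced and few, use their count so gridded layouts map
# injectively; otherwise fall back to max_size.
infer_dim <- function(z, max_size = 64) {
  u <- sort(unique(z))
  if (length(u) == 1) return(max(4L, 1L))
  if (length(u) <= max_size) {
    d <- diff(u)
    if (max(d) - min(d) <= 1e-8 * max(abs(u), 1)) return(max(4L, length(u)))
  }
  as.integer(max_size)
}

#' Map spot coordinates to raster pixels
#'
#' Linear map of x to columns `[0, W-1]` and y to rows with the vertical axis
#' flipped (largest y becomes row 0), indices rounded half-up. Several spots
#' may collide on one pixel; collisions are recorded. When `H`/`W` are `NULL`
#' they are inferred: an equally spaced coordinate grid uses its own
#' dimensions (so integer-gridded layouts are injective), anything else a
#' 64-pixel default.
#'
#' @param coords data.frame with columns `spot_id`, `x`, `y`.
#' @param H,W raster dimensions in pixels (>= 4), or `NULL` to infer.
#' @param max_size cap used during inference.
#' @return `SpotPixelMap`: list with `H`, `W`, `pixel_of_spot` (data.frame
#'   `spot_id`, `row`, `col`, zero-based), `spots_of_pixel` (list keyed by
#'   `"row,col"`), and `bbox`.
#' @export
build_pixel_map <- function(coords, H = NULL, W = NULL, max_size = 64) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("spot_id", "x", "y") %in% names(coords)), nrow(coords) >= 1)
  if (is.null(W)) W <- infer_dim(coords$x, max_size)
  if (is.null(H)) H <- infer_dim(coords$y, max_size)
  H <- as.integer(H); W <- as.integer(W)
  if (H < 1 || W < 1) stop_sf("raster dimensions must be positive")
  x <- coords$x; y <- coords$y
  xr <- range(x); yr <- range(y)
  if (diff(xr) == 0 && diff(yr) == 0 && nrow(coords) > 1)
    warning("all spots coincident; mapping to a single pixel")
  col <- if (diff(xr) == 0) rep(0L, length(x)) else
    as.integer(floor((x - xr[1]) / diff(xr) * (W - 1) + 0.5))
  row <- if (diff(yr) == 0) rep(0L, length(y)) else
    as.integer(floor((yr[2] - y) / diff(yr) * (H - 1) + 0.5))
  pix <- data.frame(spot_id = as.character(coords$spot_id),
                    row = row, col = col, stringsAsFactors = FALSE)
  key <- paste(row, col, sep = ",")
  structure(list(H = H, W = W, pixel_of_spot = pix,
                 spots_of_pixel = split(pix$spot_id, key),
                 bbox = c(x_min = xr[1], x_max = xr[2],
                          y_min = yr[1], y_max = yr[2])),
            class = "SpotPixelMap")
}

#' Global per-metric normalization bounds of a tensor
#'
#' Min and max of each metric layer over all cells and spots, so that
#' pseudo-images are comparable across cells.
#'
#' @param tensor a [build_tensor()] result.
#' @return 3 x 2 matrix with columns `lo`, `hi`.
#' @export
compute_norm_bounds <- function(tensor) {
  stopifnot(inherits(tensor, "CorrelationTensor"))
  b <- t(apply(tensor$values, 1, range))
  colnames(b) <- c("lo", "hi")
  b
}

# Scale one metric's spot values to [0,1] with clipping; a degenerate layer
# (hi == lo) maps values at the bound to 1.
scale_metric <- function(v, lo, hi) {
  if (hi <= lo) return(as.numeric(v >= hi))
  clamp((v - lo) / (hi - lo), 0, 1)
}

#' Render one cell's RGB pseudo-image
#'
#' Places the cell's three correlation row-vectors on the spot layout:
#' channel 1 (red) = MI, channel 2 (green) = R-squared, channel 3 (blue) =
#' Pearson. Values are min-max scaled to `[0, 1]` with the global per-metric
#' bounds; colliding spots contribute the mean of their scaled values;
#' non-spot pixels are exactly 0.
#'
#' @param tensor a [build_tensor()] result.
#' @param cell_index cell position in the tensor (1-based) or cell id.
#' @param map a [build_pixel_map()] result.
#' @param norm 3 x 2 bounds matrix; defaults to [compute_norm_bounds()].
#' @return `PseudoImage`: list with `channels` (`H x W x 3` array in `[0,1]`),
#'   `cell_id`, and logical background `mask` (TRUE at spot pixels).
#' @export
render_cell_image <- function(tensor, cell_index, map, norm = NULL) {
  stopifnot(inherits(tensor, "CorrelationTensor"), inherits(map, "SpotPixelMap"))
  if (is.character(cell_index))
    cell_index <- match(cell_index, tensor$cell_ids)
  if (is.na(cell_index) || cell_index < 1 || cell_index > length(tensor$cell_ids))
    stop_sf("cell_index out of range")
  if (is.null(norm)) norm <- compute_norm_bounds(tensor)
  pix <- map$pixel_of_spot
  ord <- match(pix$spot_id, tensor$spot_ids)
  if (anyNA(ord)) stop_sf("pixel map spots not present in tensor")
  key <- paste(pix$row, pix$col, sep = ",")
  channels <- array(0, dim = c(map$H, map$W, 3))
  for (i in 1:3) {
    scaled <- scale_metric(tensor$values[i, cell_index, ord], norm[i, 1], norm[i, 2])
    agg <- tapply(scaled, key, mean)
    rc <- do.call(rbind, strsplit(names(agg), ",", fixed = TRUE))
    idx <- cbind(as.integer(rc[, 1]) + 1L, as.integer(rc[, 2]) + 1L, i)
    channels[idx] <- as.numeric(agg)
  }
  mask <- matrix(FALSE, map$H, map$W)
  mask[cbind(pix$row + 1L, pix$col + 1L)] <- TRUE
  structure(list(channels = channels, cell_id = tensor$cell_ids[cell_index],
                 mask = mask),
            class = "PseudoImage")
}

#' Render pseudo-images for a set of cells
#'
#' @inheritParams render_cell_image
#' @param cells cell ids or indices; default all.
#' @return list with `images` (an `H x W x 3 x n` array), `cell_ids`, `map`,
#'   `norm`, and the shared background `mask`.
#' @export
render_images <- function(tensor, map, cells = NULL, norm = NULL) {
  if (is.null(norm)) norm <- compute_norm_bounds(tensor)
  if (is.null(cells)) cells <- tensor$cell_ids
  if (is.character(cells)) cells <- match(cells, tensor$cell_ids)
  imgs <- array(0, dim = c(map$H, map$W, 3, length(cells)))
  mask <- NULL
  for (i in seq_along(cells)) {
    im <- render_cell_image(tensor, cells[i], map, norm)
    imgs[, , , i] <- im$channels
    mask <- im$mask
  }
  list(images = imgs, cell_ids = tensor$cell_ids[cells], map = map,
       norm = norm, mask = mask)
}
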