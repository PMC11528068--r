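# LIME-style attribution: superpixel segmentation of the spot layout,
# mask perturbations, a locally weighted regression-tree surrogate, and
# aggregation of per-cell maps into cell-type attribution maps.

spot_pixels <- function(map) {
  unique(map$pixel_of_spot[c("row", "col")])
}

#' Partition the spot-bearing pixels into superpixels
#'
#' Grid tiling of the bounding box of the spot pixels; empty tiles are
#' dropped; if more than `K` tiles are nonempty the smallest segments are
#' merged into an adjacent (grid-neighbor) segment until exactly `K` remain.
#'
#' @param map a [build_pixel_map()] result.
#' @param K requested number of segments (`K <=` number of spot pixels).
#' @return `SuperpixelSegmentation`: list with `assignments` (data.frame
#'   `row`, `col`, `segment`), `K`, `method`.
#' @export
segment_superpixels <- function(map, K = 40L) {
  px <- spot_pixels(map)
  n_pix <- nrow(px)
  if (K > n_pix) stop_sf("K exceeds the number of spot pixels (", n_pix, ")")
  if (K < 1) stop_sf("K must be positive")
  rmin <- min(px$row); rmax <- max(px$row)
  cmin <- min(px$col); cmax <- max(px$col)
  hs <- rmax - rmin + 1L; ws <- cmax - cmin + 1L
  gr <- clamp(round(sqrt(K * hs / ws)), 1, hs)
  gc <- clamp(ceiling(K / gr), 1, ws)
  repeat {
    ti <- pmin(gr - 1L, ((px$row - rmin) * gr) %/% hs)
    tj <- pmin(gc - 1L, ((px$col - cmin) * gc) %/% ws)
    tile <- ti * gc + tj
    if (length(unique(tile)) >= K || (gr >= hs && gc >= ws)) break
    if (gr / hs <= gc / ws) gr <- min(hs, gr + 1L) else gc <- min(ws, gc + 1L)
  }
  seg <- as.integer(factor(tile))
  # merge the smallest segments into a grid-adjacent neighbor until K remain
  tile_of_seg <- tapply(tile, seg, function(t) t[1])
  while (length(unique(seg)) > K) {
    sizes <- table(seg)
    victim <- as.integer(names(sizes)[which.min(sizes)])
    vt <- tile_of_seg[[as.character(victim)]]
    vi <- vt %/% gc; vj <- vt %% gc
    neigh_tiles <- c(vt - gc, vt + gc, if (vj > 0) vt - 1L, if (vj < gc - 1L) vt + 1L)
    cand <- unique(seg[tile %in% neigh_tiles & seg != victim])
    if (!length(cand)) {
      # isolated: merge into the nearest segment by pixel centroid
      cent <- cbind(tapply(px$row, seg, mean), tapply(px$col, seg, mean))
      others <- setdiff(unique(seg), victim)
      dists <- rowSums((cent[as.character(others), , drop = FALSE] -
                          matrix(cent[as.character(victim), ], length(others), 2,
                                 byrow = TRUE))^2)
      cand <- others[which.min(dists)]
    }
    csz <- sizes[as.character(cand)]
    target <- cand[which.min(csz)]
    seg[seg == victim] <- target
  }
  seg <- as.integer(factor(seg))
  structure(list(assignments = data.frame(row = px$row, col = px$col,
                                          segment = seg),
                 K = length(unique(seg)), method = "grid"),
            class = "SuperpixelSegmentation")
}

# Replace the pixels of "off" segments by the per-channel mean over all spot
# pixels of the image.
perturb_image <- function(channels, seg_pixels, off_segments, channel_means) {
  for (s in off_segments) {
    idx <- seg_pixels[[s]]
    for (ch in 1:3) channels[cbind(idx, ch)] <- channel_means[ch]
  }
  channels
}

#' Explain one pseudo-image with a LIME superpixel surrogate
#'
#' Draws `n_samples` binary masks over the segments (each on with
#' probability 0.5; the all-ones mask is always included), replaces "off"
#' segments by the per-channel mean over spot pixels, scores each perturbed
#' image with the frozen model, weights samples by
#' `exp(-d_cos^2 / sigma^2)` where `d_cos` is the cosine distance between
#' the mask and the all-ones mask (`sigma = 0.25`), and fits a depth-limited
#' weighted regression tree of the target-class score on the mask bits.
#' Segment attribution is the tree's impurity importance, normalized to sum
#' to one over segments, spread uniformly over each segment's pixels. A
#' model that is constant across masks yields an all-zero map.
#'
#' @param clf `TrainedClassifier` or a plain scoring function (see
#'   [predict_scores()]).
#' @param image a `PseudoImage`.
#' @param seg a [segment_superpixels()] result.
#' @param target class to explain: class name, or column index into the
#'   score matrix.
#' @param n_samples number of perturbation draws.
#' @param seed integer seed (masks are the only randomness).
#' @param head which head's scores to explain for multilabel models.
#' @param sigma kernel width of the proximity weight.
#' @param max_depth surrogate tree depth cap (the complexity control).
#' @return `AttributionMap`: list with `values` (`H x W` grid, background 0),
#'   `cell_id`, `target`, and `segment_importance`.
#' @export
explain_image <- function(clf, image, seg, target, n_samples = 500L, seed = 0L,
                          head = 1L, sigma = 0.25, max_depth = 3L) {
  stopifnot(inherits(image, "PseudoImage"),
            inherits(seg, "SuperpixelSegmentation"))
  K <- seg$K
  asg <- seg$assignments
  seg_pixels <- lapply(split(seq_len(nrow(asg)),
                             factor(asg$segment, levels = seq_len(K))), function(i)
    cbind(asg$row[i] + 1L, asg$col[i] + 1L))
  d <- dim(image$channels)
  spot_idx <- which(image$mask)
  channel_means <- vapply(1:3, function(ch)
    mean(image$channels[, , ch][spot_idx]), numeric(1))

  masks <- withr::with_seed(seed, {
    m <- matrix(rbinom((n_samples - 1L) * K, 1L, 0.5), n_samples - 1L, K)
    rbind(rep(1L, K), m)
  })
  batch <- array(0, c(d, nrow(masks)))
  for (i in seq_len(nrow(masks))) {
    off <- which(masks[i, ] == 0)
    batch[, , , i] <- perturb_image(image$channels, seg_pixels, off,
                                    channel_means)
  }
  sc <- predict_scores(clf, batch)
  if (is.list(sc) && !is.matrix(sc)) sc <- sc[[head]]
  if (is.character(target)) {
    tcol <- match(target, colnames(sc))
    if (is.na(tcol)) stop_sf("unknown target class: ", target)
  } else tcol <- as.integer(target)
  y <- sc[, tcol]

  s <- rowSums(masks)
  cos_sim <- sqrt(s / K)                  # cosine of binary mask vs all-ones
  dcos <- 1 - cos_sim
  w <- exp(-dcos^2 / sigma^2)

  vals <- matrix(0, d[1], d[2])
  seg_imp <- numeric(K)
  if (stats::var(y) > 0) {
    fit <- fit_wtree(masks, y, w, max_depth = max_depth)
    imp <- fit$importance
    if (sum(imp) > 0) seg_imp <- imp / sum(imp)
  }
  for (si in seq_len(K)) {
    idx <- seg_pixels[[si]]
    vals[idx] <- seg_imp[si] / nrow(idx)
  }
  structure(list(values = vals, cell_id = image$cell_id,
                 target = if (is.character(target)) target else colnames(sc)[tcol],
                 segment_importance = seg_imp),
            class = "AttributionMap")
}

#' Average per-cell attribution maps by cell type
#'
#' Elementwise mean of the member maps of each type. Types present in the
#' label set but with no maps are omitted with a warning.
#'
#' @param maps list of `AttributionMap`s.
#' @param labels cell type per map (same length as `maps`).
#' @return named list of `CellTypeAttribution`s (`values`, `cell_type`,
#'   `n_cells`).
#' @export
aggregate_by_type <- function(maps, labels) {
  stopifnot(length(maps) == length(labels))
  if (!is.factor(labels)) labels <- factor(labels)
  empty <- levels(labels)[table(labels) == 0]
  if (length(empty))
    warning("types with zero cells omitted: ", paste(empty, collapse = ", "))
  out <- list()
  for (t in levels(labels)[table(labels) > 0]) {
    member <- maps[labels == t]
    acc <- Reduce(`+`, lapply(member, `[[`, "values")) / length(member)
    out[[t]] <- structure(list(values = acc, cell_type = t,
                               n_cells = length(member)),
                          class = "CellTypeAttribution")
  }
  out
}

# Per-spot attribution values of a (cell-type) attribution map.
attribution_per_spot <- function(att, map) {
  pix <- map$pixel_of_spot
  v <- att$values[cbind(pix$row + 1L, pix$col + 1L)]
  stats::setNames(v, pix$spot_id)
}

#' High-attribution spots (top fraction of attribution values)
#'
#' Spots whose attribution value is at or above the `1 - top_frac` quantile
#' of the per-spot attribution values; ties at the threshold are included.
#'
#' @param att an `AttributionMap` or `CellTypeAttribution`.
#' @param map the [build_pixel_map()] used to rasterize.
#' @param top_frac fraction in (0, 1); default the top 20%.
#' @return character vector of spot ids.
#' @export
high_attribution_spots <- function(att, map, top_frac = 0.2) {
  if (top_frac <= 0 || top_frac >= 1) stop_sf("top_frac must lie in (0, 1)")
  v <- attribution_per_spot(att, map)
  thr <- stats::quantile(v, 1 - top_frac, names = FALSE, type = 7)
  names(v)[v >= thr]
}
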