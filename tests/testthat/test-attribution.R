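make_full_map <- function(n = 10) {
  co <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  co$spot_id <- paste0("s", seq_len(nrow(co)))
  build_pixel_map(co, n, n)
}

test_that("superpixel segmentation tiles, drops and merges to exactly K", {
  map <- make_full_map(10)
  seg <- segment_superpixels(map, K = 4)
  expect_equal(seg$K, 4)
  expect_equal(unname(table(seg$assignments$segment)), rep(25L, 4),
               ignore_attr = TRUE)
  # singletons at K = number of spot pixels
  segN <- segment_superpixels(map, K = 100)
  expect_equal(segN$K, 100)
  expect_equal(max(table(segN$assignments$segment)), 1)
  expect_error(segment_superpixels(map, K = 101), "exceeds")
})

test_that("segmentation of an irregular layout is near-equal-sized and contiguous", {
  sim <- simulate_paired(synthetic_config(seed = 1))
  map <- build_pixel_map(sim$st$coords)
  K <- 40
  seg <- segment_superpixels(map, K)
  sizes <- table(seg$assignments$segment)
  expect_equal(seg$K, K)
  expect_equal(sum(sizes), nrow(unique(map$pixel_of_spot[c("row", "col")])))
  m <- mean(sizes)
  expect_true(all(sizes >= m / 2 & sizes <= 2 * m))
  # contiguity under 8-adjacency
  for (pieces in split(seq_len(nrow(seg$assignments)), seg$assignments$segment)) {
    p <- seg$assignments[pieces, ]
    if (nrow(p) == 1) next
    adj <- (abs(outer(p$row, p$row, "-")) <= 1) &
      (abs(outer(p$col, p$col, "-")) <= 1)
    reach <- adj[1, ]
    repeat {
      nxt <- (adj %*% reach > 0) | reach
      if (all(nxt == reach)) break
      reach <- nxt
    }
    expect_true(all(reach))
  }
})

oracle_for_segment <- function(seg, target_segment) {
  idx <- seg$assignments[seg$assignments$segment == target_segment, ]
  function(X) {
    n <- dim(X)[4]
    s <- vapply(seq_len(n), function(i)
      mean(X[, , 1, i][cbind(idx$row + 1, idx$col + 1)]), numeric(1))
    cbind(hit = s, miss = 1 - s)
  }
}

test_that("LIME surrogate recovers a planted segment and normalizes to one", {
  map <- make_full_map(10)
  seg <- segment_superpixels(map, K = 8)
  set.seed(2)
  img <- structure(list(channels = array(runif(300), c(10, 10, 3)),
                        cell_id = "c1", mask = matrix(TRUE, 10, 10)),
                   class = "PseudoImage")
  oracle <- oracle_for_segment(seg, 5)
  hits <- 0
  for (s in 1:20) {
    att <- explain_image(oracle, img, seg, target = "hit", n_samples = 200,
                         seed = s)
    expect_equal(sum(att$segment_importance), 1, tolerance = 1e-12)
    hits <- hits + (which.max(att$segment_importance) == 5)
  }
  expect_gte(hits, 19)
  # attribution invariant to relabeling the segment ids
  perm <- sample(8)
  seg2 <- seg
  seg2$assignments$segment <- perm[seg$assignments$segment]
  att1 <- explain_image(oracle, img, seg, target = "hit", n_samples = 200,
                        seed = 9)
  att2 <- explain_image(oracle, img, seg2, target = "hit", n_samples = 200,
                        seed = 9)
  expect_equal(which.max(att2$segment_importance),
               perm[which.max(att1$segment_importance)])
  # determinism and background zero
  att1b <- explain_image(oracle, img, seg, target = "hit", n_samples = 200,
                         seed = 9)
  expect_identical(att1$values, att1b$values)
  expect_true(all(is.finite(att1$values)))

  # constant model explains to an all-zero map
  const <- function(X) cbind(hit = rep(0.4, dim(X)[4]), miss = 0.6)
  attc <- explain_image(const, img, seg, target = "hit", n_samples = 50,
                        seed = 1)
  expect_true(all(attc$values == 0))
  expect_equal(sum(attc$segment_importance), 0)
})

test_that("sampled surrogate agrees with the exhaustive 16-mask fit at K = 4", {
  map <- make_full_map(8)
  seg <- segment_superpixels(map, K = 4)
  set.seed(7)
  img <- structure(list(channels = array(runif(192), c(8, 8, 3)),
                        cell_id = "c1", mask = matrix(TRUE, 8, 8)),
                   class = "PseudoImage")
  oracle <- oracle_for_segment(seg, 3)
  att <- explain_image(oracle, img, seg, target = "hit", n_samples = 500,
                       seed = 0)
  # exhaustive enumeration of all 2^4 masks, same weighting scheme
  masks <- as.matrix(expand.grid(rep(list(0:1), 4)))
  seg_px <- split(seq_len(nrow(seg$assignments)), seg$assignments$segment)
  mu <- vapply(1:3, function(ch) mean(img$channels[, , ch]), numeric(1))
  ys <- apply(masks, 1, function(m) {
    pert <- img$channels
    for (s in which(m == 0)) {
      p <- seg$assignments[seg_px[[s]], ]
      for (ch in 1:3) pert[cbind(p$row + 1, p$col + 1, ch)] <- mu[ch]
    }
    oracle(array(pert, c(8, 8, 3, 1)))[1, "hit"]
  })
  w <- exp(-(1 - sqrt(rowSums(masks) / 4))^2 / 0.25^2)
  fit <- spotfuse:::fit_wtree(masks, ys, w, max_depth = 3)
  expect_equal(which.max(att$segment_importance), which.max(fit$importance))
  expect_equal(which.max(fit$importance), 3L)
})

test_that("aggregation averages elementwise and is linear", {
  g <- function(v) structure(list(values = matrix(v, 2, 2), cell_id = "x",
                                  target = "A", segment_importance = NULL),
                             class = "AttributionMap")
  maps <- list(g(0), g(0.3), g(0.6), g(1))
  agg <- aggregate_by_type(maps, c("A", "A", "A", "B"))
  expect_equal(agg$A$values, matrix(0.3, 2, 2))
  expect_equal(agg$B$values, matrix(1, 2, 2))
  expect_equal(agg$A$n_cells, 3)
  # single map per type passes through; equal maps average to themselves
  agg2 <- aggregate_by_type(list(g(0.5), g(0.5)), c("A", "A"))
  expect_equal(agg2$A$values, matrix(0.5, 2, 2))
  # zero-cell types are dropped with a warning
  expect_warning(aggregate_by_type(maps, factor(rep("A", 4),
                                                levels = c("A", "Z"))), "Z")
  # linearity: mean over the union of equal groups = mean of group means
  u1 <- aggregate_by_type(maps[1:2], c("A", "A"))$A$values
  u2 <- aggregate_by_type(maps[3:4], c("A", "A"))$A$values
  all4 <- aggregate_by_type(maps, rep("A", 4))$A$values
  expect_equal(all4, (u1 + u2) / 2)
})

test_that("high-attribution spots follow the top-quantile rule with ties", {
  co <- data.frame(spot_id = paste0("s", 1:10), x = 0:9, y = 0)
  map <- build_pixel_map(co, 4, 10)
  att <- structure(list(values = matrix(0, 4, 10), cell_type = "A",
                        n_cells = 1), class = "CellTypeAttribution")
  px <- map$pixel_of_spot
  vals <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10) / 10
  att$values[cbind(px$row + 1, px$col + 1)] <- vals
  top <- high_attribution_spots(att, map, 0.2)
  expect_setequal(top, c("s3", "s10"))
  # all equal -> all returned
  att$values[cbind(px$row + 1, px$col + 1)] <- 0.5
  expect_setequal(high_attribution_spots(att, map, 0.2), co$spot_id)
  # larger instance against a sort-based oracle
  co2 <- data.frame(spot_id = paste0("s", 1:100), x = rep(0:9, 10),
                    y = rep(0:9, each = 10))
  map2 <- build_pixel_map(co2, 10, 10)
  set.seed(5)
  v2 <- sample(seq(0.01, 1, length.out = 100))
  att2 <- structure(list(values = matrix(0, 10, 10)), class = "CellTypeAttribution")
  px2 <- map2$pixel_of_spot
  att2$values[cbind(px2$row + 1, px2$col + 1)] <- v2
  top2 <- high_attribution_spots(att2, map2, 0.2)
  oracle <- co2$spot_id[order(v2, decreasing = TRUE)[1:20]]
  expect_setequal(top2, oracle)
})
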