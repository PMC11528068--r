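test_that("fusion averages normalized layers and profiles types by mean row", {
  # hand tensor: 3 cells (A, A, B) x 2 spots
  vals <- array(0, c(3, 3, 2), dimnames = list(c("MI", "R2", "PCC"),
                                               c("c1", "c2", "c3"),
                                               c("s1", "s2")))
  vals[1, , ] <- matrix(c(0, 2, 4, 6, 8, 10), 3, 2)      # min 0 max 10
  vals[2, , ] <- matrix(c(1, 1, 1, 0, 0, 0), 3, 2)       # min 0 max 1
  vals[3, , ] <- matrix(c(-1, 0, 1, 1, 0, -1), 3, 2)     # min -1 max 1
  tn <- fake_tensor(vals, c("c1", "c2", "c3"), c("s1", "s2"))
  labels <- c(c1 = "A", c2 = "A", c3 = "B")
  prof <- fuse_and_profile(tn, labels)
  # looped oracle: min-max each layer, average layers, average cells per type
  norm <- apply(vals, 1, function(l) (l - min(l)) / (max(l) - min(l)))
  wbar <- matrix(rowMeans(norm), 3, 2)
  expect_equal(unname(prof["A", ]), colMeans(wbar[1:2, ]))
  expect_equal(unname(prof["B", ]), wbar[3, ])

  # all three layers identical -> fused equals the normalized layer
  vals2 <- vals; vals2[2, , ] <- vals[1, , ]; vals2[3, , ] <- vals[1, , ]
  tn2 <- fake_tensor(vals2, c("c1", "c2", "c3"), c("s1", "s2"))
  prof2 <- fuse_and_profile(tn2, labels)
  nl <- (vals[1, , ] - 0) / 10
  expect_equal(unname(prof2["B", ]), unname(nl[3, ]))
  # single-cell type: profile equals that cell's fused row
  expect_equal(unname(prof["B", ]), wbar[3, ])
  # raw mode skips normalization
  prof_raw <- fuse_and_profile(tn, labels, fuse = "raw")
  wraw <- apply(vals, c(2, 3), mean)
  expect_equal(unname(prof_raw["B", ]), unname(wraw[3, ]))
  expect_error(fuse_and_profile(tn, c(c1 = "A", c2 = "A", c3 = NA)), "label")
})

test_that("proportions land on the simplex with the stated degeneracy rules", {
  prof <- matrix(c(0.6, 0.3, 0.1, 0.2, 0.2, 0.6), 3, 2,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  p <- spot_proportions(prof)
  expect_equal(unname(p$values["s1", ]), c(0.6, 0.3, 0.1))
  expect_equal(rowSums(p$values), c(s1 = 1, s2 = 1), tolerance = 1e-9)
  expect_equal(p$predominant, c("A", "C"))

  # q = 1 gives certainty; symmetric profile gives 0.5/0.5
  p1 <- spot_proportions(matrix(c(2, 5), 1, 2,
                                dimnames = list("A", c("s1", "s2"))))
  expect_equal(unname(p1$values[, "A"]), c(1, 1))
  psym <- spot_proportions(matrix(c(0.2, 0.2), 2, 1,
                                  dimnames = list(c("A", "B"), "s1")))
  expect_equal(unname(psym$values["s1", ]), c(0.5, 0.5))
  # argmax tie -> lexicographically first type
  expect_equal(psym$predominant, "A")

  # negatives clipped, all-zero rows -> uniform with warning
  prof_neg <- matrix(c(-1, 2, -3, -4), 2, 2,
                     dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_warning(pz <- spot_proportions(prof_neg), "uniform")
  expect_equal(unname(pz$values["s1", ]), c(0, 1))
  expect_equal(unname(pz$values["s2", ]), c(0.5, 0.5))

  # random profiles: simplex property
  set.seed(8)
  for (i in 1:20) {
    pr <- matrix(rnorm(4 * 7), 4, 7,
                 dimnames = list(LETTERS[1:4], paste0("s", 1:7)))
    pp <- suppressWarnings(spot_proportions(pr))
    expect_true(all(pp$values >= 0))
    expect_equal(rowSums(pp$values), rep(1, 7), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("type permutation equivariance and cell-order invariance hold", {
  sim <- sim_small()
  tn <- build_tensor(sim$sc, sim$st)
  labels <- setNames(sim$sc$labels$cell_type, sim$sc$cell_ids)
  prof <- fuse_and_profile(tn, labels)
  # reordering cells within types leaves profiles unchanged (labels named)
  perm <- sample(length(labels))
  prof2 <- fuse_and_profile(tn, labels[perm])
  expect_equal(prof, prof2)
})

test_that("ARI matches hand values and the pair-counting oracle", {
  expect_equal(ari(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(ari(c("a", "a", "b", "b"), c("a", "b", "a", "b")), -0.5)
  expect_equal(ari(rep("x", 6), rep("y", 6)), 1)  # both sides one cluster
  expect_error(ari(character(0), character(0)), "empty")
  expect_error(ari(1:3, 1:4), "mismatch")
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(a, b), ari_pair_oracle(a, b), tolerance = 1e-12)
  }
})
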