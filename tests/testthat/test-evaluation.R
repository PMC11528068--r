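test_that("metric identities hold at their fixed points", {
  x <- c(0.1, 0.3, 0.6, 0.2, 0.5)
  expect_equal(pcc_per_type(x, x), 1)
  expect_equal(ssim(x, x), 1)
  expect_equal(rmse(x, x), 0)
  expect_equal(jsd(x, x), 0)
  # two-type complement is perfectly anticorrelated
  expect_equal(pcc_per_type(x, 1 - x), -1)
  # zero-variance pair at equal means: stabilizers dominate, SSIM = 1
  expect_equal(ssim(rep(0.4, 5), rep(0.4, 5)), 1)
})

test_that("metrics match direct-sum / hand oracles on small vectors", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(50); b <- runif(50)
    expect_equal(pcc_per_type(a, b), pearson_oracle(a, b), tolerance = 1e-12)
    # rmse against an explicit loop with population z-scores
    za <- (a - mean(a)) / sqrt(mean((a - mean(a))^2))
    zb <- (b - mean(b)) / sqrt(mean((b - mean(b))^2))
    expect_equal(rmse(a, b), sqrt(sum((za - zb)^2) / 50), tolerance = 1e-12)
  }
  # z-scored truth against its negation: RMS of a population z-vector is 1
  v <- c(1, 2, 3, 6)
  zt <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  expect_equal(rmse(v, rep(0, 4)) >= 0, TRUE)
  expect_equal(sqrt(mean((zt - (-zt))^2)), 2)
  expect_equal(rmse(c(1, 2, 3, 6), -c(1, 2, 3, 6)), 2)

  # SSIM by direct arithmetic on the hand pair (0.2, 0.4) vs (0.4, 0.2)
  xs <- c(0.2, 0.4) / 0.4; ys <- c(0.4, 0.2) / 0.4
  mx <- mean(xs); my <- mean(ys)
  vx <- mean((xs - mx)^2); vy <- mean((ys - my)^2)
  cv <- mean((xs - mx) * (ys - my))
  hand <- ((2 * mx * my + 0.01^2) * (2 * cv + 0.03^2)) /
    ((mx^2 + my^2 + 0.01^2) * (vx + vy + 0.03^2))
  expect_equal(ssim(c(0.2, 0.4), c(0.4, 0.2)), hand, tolerance = 1e-12)

  # JSD: hand value for (.5, .5) vs (1, 0); disjoint supports reach the bound
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)),
               0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)) +
                 0.5 * log2(1 / 0.75) * 0.5 * 2,
               tolerance = 1e-9)
  expect_equal(jsd(c(1, 0, 0), c(0, 0.5, 0.5)), 1)
  # symmetry and spot-permutation invariance
  a <- runif(30); b <- runif(30)
  expect_equal(jsd(a, b), jsd(b, a))
  p <- sample(30)
  expect_equal(jsd(a[p], b[p]), jsd(a, b))
  expect_equal(ssim(a[p], b[p]), ssim(a, b))
})

test_that("metric preconditions are enforced", {
  expect_error(ssim(c(0, 0), c(1, 2)), "all-zero")
  expect_error(jsd(c(0, 0), c(1, 2)), "zero-sum")
  expect_error(jsd(c(-1, 2), c(1, 2)), "nonnegative")
  expect_error(pcc_per_type(1:5, 1:4), "mismatch")
})

test_that("performance levels rank as stated and APS aggregates them", {
  tab <- data.frame(PCC = c(0.9, 0.5, 0.1),
                    SSIM = c(0.8, 0.6, 0.2),
                    RMSE = c(0.1, 0.5, 0.9),
                    JSD = c(0.05, 0.2, 0.6),
                    row.names = c("best", "mid", "worst"))
  r <- aps(tab)
  expect_equal(unname(r$APS["best"]), 3)   # dominates all four -> Q
  expect_equal(unname(r$APS["worst"]), 1)
  expect_equal(unname(colSums(r$PL)), rep(6, 4))  # Q(Q+1)/2 conservation

  # tie handling: mean rank, checked against a sort-based oracle
  tab2 <- data.frame(PCC = c(0.9, 0.9, 0.1),
                     SSIM = c(0.7, 0.6, 0.2),
                     RMSE = c(0.3, 0.3, 0.9),
                     JSD = c(0.1, 0.2, 0.6),
                     row.names = c("m1", "m2", "m3"))
  r2 <- aps(tab2)
  expect_equal(unname(r2$PL[, "PCC"]), c(2.5, 2.5, 1))
  expect_equal(unname(r2$PL[, "RMSE"]), c(2.5, 2.5, 1))
  expect_equal(unname(r2$APS["m1"]), mean(c(2.5, 3, 2.5, 3)))
  expect_error(aps(tab[, 1:3]), "missing")
})

test_that("evaluate_deconvolution scores per type over shared spots", {
  sim <- sim_small()
  tn <- build_tensor(sim$sc, sim$st)
  pr <- deconvolve(tn, setNames(sim$sc$labels$cell_type, sim$sc$cell_ids))
  ev <- evaluate_deconvolution(pr, sim$truth$values)
  expect_equal(nrow(ev), 3)
  expect_true(all(c("PCC", "SSIM", "RMSE", "JSD") %in% names(ev)))
  expect_true(all(is.finite(unlist(ev[-1]))))
  expect_true(all(ev$JSD >= 0 & ev$JSD <= 1))
  # perfect prediction scores at the fixed points
  ev0 <- evaluate_deconvolution(sim$truth$values, sim$truth$values)
  expect_equal(ev0$PCC, rep(1, 3))
  expect_equal(ev0$RMSE, rep(0, 3))
  expect_equal(ev0$JSD, rep(0, 3))
})
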