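test_that("paired loading round-trips CSV and MTX encodings identically", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1, 0, 2, 0,
                0, 3, 0, 1,
                4, 0, 0, 2), 3, 4, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  Y <- matrix(c(2, 1, 0, 0,
                0, 0, 3, 1), 2, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:2), paste0("g", 1:4)))
  coords <- data.frame(spot_id = c("s1", "s2"), x = c(0, 1), y = c(0, 1))
  labels <- data.frame(cell_id = paste0("c", 1:3), cell_type = c("A", "B", "A"))
  write.table(data.frame(id = rownames(X), X), file.path(dir, "sc.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write.table(data.frame(id = rownames(Y), Y), file.path(dir, "st.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  ds <- load_paired_dataset(file.path(dir, "sc.csv"), file.path(dir, "st.csv"),
                            file.path(dir, "coords.tsv"),
                            file.path(dir, "labels.tsv"))
  expect_equal(dim(ds$sc), c(3L, 4L))
  expect_equal(dim(ds$st), c(2L, 4L))
  expect_equal(unname(ds$sc$values), unname(X))

  # same matrix as MatrixMarket triplets must parse to identical content
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), file.path(dir, "sc.mtx"))
  writeLines(rownames(X), file.path(dir, "sc.rownames.txt"))
  writeLines(colnames(X), file.path(dir, "sc.colnames.txt"))
  ds2 <- load_paired_dataset(file.path(dir, "sc.mtx"), file.path(dir, "st.csv"),
                             file.path(dir, "coords.tsv"),
                             file.path(dir, "labels.tsv"))
  expect_equal(ds2$sc$values, ds$sc$values)

  # label validation names the offending cell
  labels_bad <- labels[1:2, ]
  write.table(labels_bad, file.path(dir, "labels_bad.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_paired_dataset(file.path(dir, "sc.csv"),
                                   file.path(dir, "st.csv"),
                                   file.path(dir, "coords.tsv"),
                                   file.path(dir, "labels_bad.tsv")),
               "c3")
  # spot absent from coords
  write.table(coords[1, ], file.path(dir, "coords_bad.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_paired_dataset(file.path(dir, "sc.csv"),
                                   file.path(dir, "st.csv"),
                                   file.path(dir, "coords_bad.tsv"),
                                   file.path(dir, "labels.tsv")),
               "s2")
  # negative values rejected
  Xn <- X; Xn[1, 1] <- -1
  write.table(data.frame(id = rownames(Xn), Xn), file.path(dir, "sc_neg.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(load_paired_dataset(file.path(dir, "sc_neg.csv"),
                                   file.path(dir, "st.csv"),
                                   file.path(dir, "coords.tsv"),
                                   file.path(dir, "labels.tsv")),
               "nonnegative")
})

test_that("gene filtering applies the prevalence thresholds with >= and intersects", {
  # 6 genes with cell prevalences 100%, 60%, 5%, 4%, 0% and a spot-only
  # dropout at 0.5%: exactly 3 genes must survive at the default thresholds.
  n1 <- 100; n2 <- 200
  genes <- paste0("g", 1:6)
  X <- matrix(0, n1, 6, dimnames = list(paste0("c", 1:n1), genes))
  X[, 1] <- 1
  X[1:60, 2] <- 2
  X[1:5, 3] <- 1          # exactly 5% of cells: survives (removal is "fewer than")
  X[1:4, 4] <- 1          # 4% of cells: removed
  X[1:80, 6] <- 1         # fine in cells, fails in spots
  Y <- matrix(0, n2, 6, dimnames = list(paste0("s", 1:n2), genes))
  Y[, 1] <- 1
  Y[1:100, 2] <- 1
  Y[1:10, 3] <- 1
  Y[1:10, 4] <- 1
  Y[1, 6] <- 1            # 0.5% of spots < 1%: removed
  sc <- gene_expression_matrix(X, labels = data.frame(
    cell_type = rep("A", n1), row.names = rownames(X)))
  st <- spatial_dataset(Y, coords = data.frame(spot_id = rownames(Y),
                                               x = seq_len(n2), y = 0))
  out <- filter_and_align(sc, st)
  expect_identical(out$sc$gene_ids, c("g1", "g2", "g3"))
  expect_identical(out$sc$gene_ids, out$st$gene_ids)

  # idempotence and no growth of expressed entries
  out2 <- filter_and_align(out$sc, out$st)
  expect_equal(out2$sc$values, out$sc$values)
  expect_equal(out2$st$values, out$st$values)
  expect_lte(sum(out$sc$values > 0), sum(X > 0))

  # empty survivor set advises relaxation (no gene reaches 50% of cells)
  Xs <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, 1, 0,
                 0, 0, 0, 1), 4, 4,
               dimnames = list(paste0("c", 1:4), paste0("g", 1:4)))
  scs <- gene_expression_matrix(Xs, labels = data.frame(
    cell_type = rep("A", 4), row.names = rownames(Xs)))
  sts <- spatial_dataset(Xs, coords = data.frame(spot_id = rownames(Xs),
                                                 x = 1:4, y = 0))
  expect_error(filter_and_align(scs, sts, cell_frac = 0.5, spot_frac = 0.5),
               "relax")
  expect_error(filter_and_align(sc, st, cell_frac = 0), "\\(0, 1\\)")
})

test_that("fixture writer emits files the loader accepts, in both formats", {
  sim <- sim_small()
  for (fmt in c("csv", "mtx")) {
    dir <- withr::local_tempdir()
    paths <- write_fixture(sim, dir, format = fmt)
    ds <- load_paired_dataset(paths[["sc"]], paths[["st"]], paths[["coords"]],
                              paths[["labels"]])
    expect_equal(ds$sc$values, sim$sc$values)
    expect_equal(ds$st$values, sim$st$values)
    expect_identical(ds$sc$labels$cell_type, sim$sc$labels$cell_type)
  }
})
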