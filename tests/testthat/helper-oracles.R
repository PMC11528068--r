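# Independent oracles, deliberately written against the raw formula sums so
# they share no code path with the package implementations.

# Direct-sum Pearson correlation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Pair-counting adjusted Rand index (O(n^2) brute force).
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Exhaustive hypergeometric upper tail: fraction of all H-subsets of 1..M
# whose overlap with 1..N is at least C.
hyper_enum_oracle <- function(M, N, H, C) {
  if (H == 0) return(as.numeric(C == 0))
  subsets <- utils::combn(M, H)
  mean(colSums(subsets <= N) >= C)
}

# Cosine similarity by raw sums.
cosine_oracle <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small synthetic paired fixture for module tests (fast).
sim_small <- function(q = 3, n_cells = 240, m = 60, grid = c(8, 8), seed = 1) {
  simulate_paired(synthetic_config(q = q, m = m, signature_genes_per_type = 6,
                                   n_cells = n_cells, grid = grid, seed = seed))
}

# Minimal hand-made paired objects.
toy_paired <- function() {
  genes <- paste0("g", 1:6)
  X <- matrix(c(5, 0, 1, 0, 2, 0,
                0, 3, 2, 1, 0, 0,
                4, 1, 0, 0, 0, 0,
                2, 2, 3, 0, 1, 0), 4, 6, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), genes))
  Y <- matrix(c(3, 1, 0, 2, 1, 0,
                0, 2, 4, 0, 0, 0,
                1, 1, 1, 1, 1, 0), 3, 6, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), genes))
  sc <- gene_expression_matrix(X, labels = data.frame(
    cell_type = c("A", "A", "B", "B"), row.names = rownames(X)))
  st <- spatial_dataset(Y, coords = data.frame(
    spot_id = rownames(Y), x = c(0, 1, 2), y = c(0, 1, 0)))
  list(sc = sc, st = st)
}

# Fabricate a CorrelationTensor directly (fields only; used to exercise the
# imaging module with hand-chosen values).
fake_tensor <- function(vals, cell_ids, spot_ids) {
  structure(list(values = vals, metric_names = c("MI", "R2", "PCC"),
                 cell_ids = cell_ids, spot_ids = spot_ids,
                 rho2_clamp = 1e-12),
            class = "CorrelationTensor")
}
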