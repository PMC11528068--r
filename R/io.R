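# File formats: dense CSV/TSV (header row = gene ids, first column = cell or
# spot ids) and MatrixMarket triplets (<stem>.mtx + <stem>.rownames.txt +
# <stem>.colnames.txt, rows = cells/spots, columns = genes). Coordinates and
# labels are TSV.

read_id_file <- function(path) {
  if (!file.exists(path)) stop_sf("missing index file: ", path)
  scan(path, what = character(), quiet = TRUE, sep = "\n")
}

# Read one expression matrix in either encoding; rows carry the observation
# ids, columns the gene ids.
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_sf("missing file: ", path)
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(path))
    rn <- read_id_file(paste0(stem, ".rownames.txt"))
    cn <- read_id_file(paste0(stem, ".colnames.txt"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop_sf("index files do not match matrix dimensions for ", path)
    dimnames(m) <- list(rn, cn)
    m
  } else {
    sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    as.matrix(df)
  }
}

orient_to_rows <- function(m, expected_ids, what) {
  hit_rows <- mean(expected_ids %in% rownames(m))
  hit_cols <- mean(expected_ids %in% colnames(m))
  if (hit_cols > hit_rows) m <- t(m)
  m
}

#' Load a paired single-cell + spatial dataset from disk
#'
#' Reads the four files of a paired dataset, normalizes orientation to
#' cells x genes / spots x genes, and validates ids, labels and coordinates.
#'
#' @param sc_path single-cell matrix (dense CSV/TSV or `.mtx` triplet with
#'   `<stem>.rownames.txt` / `<stem>.colnames.txt` index files).
#' @param st_path spatial matrix, same formats.
#' @param coords_path TSV with columns `spot_id`, `x`, `y`.
#' @param labels_path TSV with columns `cell_id`, `cell_type` and optionally
#'   further label columns (e.g. `stage`).
#' @return list with elements `sc` ([gene_expression_matrix()]) and `st`
#'   ([spatial_dataset()]).
#' @export
load_paired_dataset <- function(sc_path, st_path, coords_path, labels_path) {
  for (p in c(sc_path, st_path, coords_path, labels_path))
    if (!file.exists(p)) stop_sf("missing file: ", p)
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  if (!"cell_id" %in% names(labels)) stop_sf("labels file needs a cell_id column")
  rownames(labels) <- as.character(labels$cell_id)
  labels$cell_id <- NULL
  coords <- utils::read.delim(coords_path, stringsAsFactors = FALSE)

  sc_m <- orient_to_rows(read_expression_matrix(sc_path), rownames(labels), "cells")
  st_m <- orient_to_rows(read_expression_matrix(st_path),
                         as.character(coords$spot_id), "spots")
  missing_lab <- setdiff(rownames(sc_m), rownames(labels))
  if (length(missing_lab))
    stop_sf("cells missing from labels: ", paste(missing_lab, collapse = ", "))
  sc <- gene_expression_matrix(sc_m, labels = labels)
  st <- spatial_dataset(st_m, coords = coords)
  list(sc = sc, st = st)
}

write_expression_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
}

write_expression_mtx <- function(m, path) {
  stem <- sub("\\.mtx$", "", path)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  writeLines(rownames(m), paste0(stem, ".rownames.txt"))
  writeLines(colnames(m), paste0(stem, ".colnames.txt"))
}

#' Write a simulated paired dataset in the on-disk formats
#'
#' Emits exactly the files [load_paired_dataset()] consumes, plus the
#' ground-truth per-spot proportions of the simulation.
#'
#' @param sim output of [simulate_paired()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"mtx"` for the two expression matrices.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "csv") ".csv" else ".mtx"
  paths <- c(sc = file.path(dir, paste0("sc", ext)),
             st = file.path(dir, paste0("st", ext)),
             coords = file.path(dir, "coords.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.csv"))
  wr <- if (format == "csv") write_expression_csv else write_expression_mtx
  wr(sim$sc$values, paths[["sc"]])
  wr(sim$st$values, paths[["st"]])
  utils::write.table(sim$st$coords, paths[["coords"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  lab <- data.frame(cell_id = sim$sc$cell_ids, sim$sc$labels,
                    check.names = FALSE)
  utils::write.table(lab, paths[["labels"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_expression_csv(sim$truth$values, paths[["truth"]])
  invisible(paths)
}
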