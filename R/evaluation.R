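# Deconvolution benchmark metrics: per-type PCC, SSIM, RMSE, JSD, and the
# rank-based aggregative performance score (APS). SSIM/RMSE moments use
# population (1/n) scaling; JSD uses base-2 logs so its range is [0, 1].

check_cols <- function(p, truth, min_n = 2L) {
  if (length(p) != length(truth)) stop_sf("length mismatch")
  if (length(p) < min_n) stop_sf("need at least ", min_n, " spots")
}

#' Per-type Pearson correlation between predicted and true proportions
#'
#' Sample correlation over spots (`n2 - 1` denominator). A constant column
#' gives 0 (flagged).
#'
#' @param p,truth numeric columns over the same spots.
#' @return scalar in \[-1, 1\].
#' @export
pcc_per_type <- function(p, truth) {
  check_cols(p, truth, 3L)
  pearson_cor(p, truth)
}

#' Structural similarity between proportion columns
#'
#' Both columns are scaled by their own maxima, then the single-window SSIM
#' formula is evaluated with stabilizers `alpha = 0.01`, `beta = 0.03` and
#' population moments.
#'
#' @inheritParams pcc_per_type
#' @param alpha,beta stabilizing constants.
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(p, truth, alpha = 0.01, beta = 0.03) {
  check_cols(p, truth)
  if (any(p < 0) || any(truth < 0)) stop_sf("proportions must be nonnegative")
  if (max(p) == 0 || max(truth) == 0)
    stop_sf("all-zero column: max scaling undefined")
  x <- p / max(p); y <- truth / max(truth)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cv <- mean((x - mx) * (y - my))
  ((2 * mx * my + alpha^2) * (2 * cv + beta^2)) /
    ((mx^2 + my^2 + alpha^2) * (vx + vy + beta^2))
}

zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    flag_note("zero-variance column in rmse; z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Root-mean-square error of z-scored proportion columns
#'
#' Both columns are z-scored with population (1/n) scaling (a zero-variance
#' column becomes all zeros, flagged), then the root-mean-square difference
#' is returned.
#'
#' @inheritParams pcc_per_type
#' @return nonnegative scalar.
#' @export
rmse <- function(p, truth) {
  check_cols(p, truth)
  sqrt(mean((zscore_pop(p) - zscore_pop(truth))^2))
}

kl_base2 <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence between spatial proportion distributions
#'
#' Columns are normalized to probability vectors over spots, then the JSD is
#' computed with base-2 logarithms (`0 * log 0 = 0`), bounding the value in
#' `[0, 1]`.
#'
#' @inheritParams pcc_per_type
#' @return scalar in \[0, 1\].
#' @export
jsd <- function(p, truth) {
  check_cols(p, truth)
  if (any(p < 0) || any(truth < 0)) stop_sf("proportions must be nonnegative")
  if (sum(p) == 0 || sum(truth) == 0) stop_sf("zero-sum column")
  P <- p / sum(p); Q <- truth / sum(truth)
  M <- (P + Q) / 2
  0.5 * kl_base2(P, M) + 0.5 * kl_base2(Q, M)
}

#' Performance levels and aggregative performance score
#'
#' Ranks `Q` methods per metric for one cell type: for PCC and SSIM the
#' highest value gets level `Q`, for RMSE and JSD the lowest value gets
#' level `Q`; ties receive the mean rank. The APS of a method is the mean of
#' its four levels.
#'
#' @param metric_table data.frame/matrix with one row per method (rownames =
#'   method names) and columns `PCC`, `SSIM`, `RMSE`, `JSD`.
#' @return list with `PL` (levels matrix) and `APS` (named vector).
#' @export
aps <- function(metric_table) {
  metric_table <- as.data.frame(metric_table)
  need <- c("PCC", "SSIM", "RMSE", "JSD")
  if (!all(need %in% names(metric_table)))
    stop_sf("missing metric columns: ",
            paste(setdiff(need, names(metric_table)), collapse = ", "))
  if (nrow(metric_table) < 2) stop_sf("need at least 2 methods to rank")
  PL <- cbind(PCC = rank(metric_table$PCC),
              SSIM = rank(metric_table$SSIM),
              RMSE = rank(-metric_table$RMSE),
              JSD = rank(-metric_table$JSD))
  rownames(PL) <- rownames(metric_table)
  list(PL = PL, APS = rowMeans(PL))
}

#' Score a proportion matrix against ground truth
#'
#' Per-type PCC, SSIM, RMSE and JSD between predicted and true proportion
#' columns over the shared spots.
#'
#' @param pred,truth `ProportionMatrix` objects (or plain spots x types
#'   matrices with dimnames) over the same spots and types.
#' @return data.frame with one row per cell type.
#' @export
evaluate_deconvolution <- function(pred, truth) {
  pm <- if (inherits(pred, "ProportionMatrix")) pred$values else as.matrix(pred)
  tm <- if (inherits(truth, "ProportionMatrix")) truth$values else as.matrix(truth)
  spots <- intersect(rownames(pm), rownames(tm))
  types <- intersect(colnames(pm), colnames(tm))
  if (!length(spots) || !length(types))
    stop_sf("no shared spots/types between prediction and truth")
  res <- data.frame(type = types,
                    PCC = NA_real_, SSIM = NA_real_,
                    RMSE = NA_real_, JSD = NA_real_)
  for (i in seq_along(types)) {
    a <- pm[spots, types[i]]; b <- tm[spots, types[i]]
    res$PCC[i] <- pcc_per_type(a, b)
    res$SSIM[i] <- ssim(a, b)
    res$RMSE[i] <- rmse(a, b)
    res$JSD[i] <- jsd(a, b)
  }
  res
}
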