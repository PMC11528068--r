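# Spot-cell similarity metrics. The mutual information uses the bivariate
# Gaussian closed form 0.5*log(var(u)*var(v)/det(Sigma)) = -0.5*log(1-rho^2),
# in nats, with rho^2 clamped below 1 so collinear pairs stay finite.

check_pair <- function(u, v) {
  if (length(u) != length(v)) stop_sf("vectors differ in length")
  if (length(u) < 3) stop_sf("need at least 3 paired values")
  if (!all(is.finite(u)) || !all(is.finite(v))) stop_sf("non-finite values")
}

#' Gaussian mutual information between two expression vectors
#'
#' Closed-form MI of a bivariate Gaussian fitted to the paired values:
#' `-0.5 * log(1 - rho^2)` nats, with `rho` the sample Pearson correlation
#' and `rho^2` clamped at `1 - 1e-12` (an upper bound of ~13.8 nats for
#' collinear pairs). Returns 0 when either vector is constant.
#'
#' @param u,v numeric vectors of equal length >= 3.
#' @return nonnegative scalar.
#' @export
mutual_information <- function(u, v) {
  check_pair(u, v)
  su <- sum((u - mean(u))^2); sv <- sum((v - mean(v))^2)
  if (su == 0 || sv == 0) return(0)
  rho <- sum((u - mean(u)) * (v - mean(v))) / sqrt(su * sv)
  -0.5 * log(max(1 - rho * rho, MI_RHO2_EPS))
}

#' Coefficient of determination of v as a direct prediction of u
#'
#' `1 - sum((u - v)^2) / sum((u - mean(u))^2)`. Asymmetric in its arguments
#' (v plays the role of the prediction) and unbounded below. Defined as 0
#' (flagged) when u is constant, since the denominator vanishes.
#'
#' @inheritParams mutual_information
#' @return scalar <= 1.
#' @export
r_squared <- function(u, v) {
  check_pair(u, v)
  den <- sum((u - mean(u))^2)
  if (den == 0) {
    flag_note("constant u in r_squared; returning 0")
    return(0)
  }
  1 - sum((u - v)^2) / den
}

#' Sample Pearson correlation
#'
#' The standard product-moment correlation with the `m - 1` denominator.
#' Either vector constant gives 0 (flagged).
#'
#' @inheritParams mutual_information
#' @return scalar in \[-1, 1\].
#' @export
pearson_cor <- function(u, v) {
  check_pair(u, v)
  uc <- u - mean(u); vc <- v - mean(v)
  su <- sum(uc^2); sv <- sum(vc^2)
  if (su == 0 || sv == 0) {
    flag_note("constant vector in pearson_cor; returning 0")
    return(0)
  }
  clamp(sum(uc * vc) / sqrt(su * sv), -1, 1)
}

#' Build the 3 x cells x spots correlation tensor
#'
#' Computes all three similarity matrices between every cell of `sc` and
#' every spot of `st` over the common (aligned) genes. Layer order is fixed:
#' 1 = mutual information, 2 = R-squared, 3 = Pearson. Vectorized; agrees
#' with the scalar metrics elementwise.
#'
#' @param sc a [gene_expression_matrix()].
#' @param st a [spatial_dataset()] with genes in identical order.
#' @return `CorrelationTensor`: list with `values` (array `3 x n1 x n2`),
#'   `metric_names`, `cell_ids`, `spot_ids`.
#' @export
build_tensor <- function(sc, st) {
  stopifnot(inherits(sc, "GeneExpressionMatrix"), inherits(st, "SpatialDataset"))
  if (!identical(sc$gene_ids, st$gene_ids))
    stop_sf("gene sets are not aligned; run filter_and_align first")
  X <- sc$values; Y <- st$values
  m <- ncol(X)
  if (m < 3) stop_sf("need at least 3 common genes")
  n1 <- nrow(X); n2 <- nrow(Y)
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  ssx <- rowSums(Xc^2); ssy <- rowSums(Yc^2)
  cross_c <- Xc %*% t(Yc)                        # centered cross products
  den <- sqrt(outer(ssx, ssy))
  pcc <- ifelse(den > 0, cross_c / den, 0)
  pcc <- clamp(pcc, -1, 1)
  mi <- -0.5 * log(pmax(1 - pcc * pcc, MI_RHO2_EPS))
  mi[den == 0] <- 0
  # R^2: residual sum expands as |u|^2 + |v|^2 - 2 u.v on the raw values
  cross_r <- X %*% t(Y)
  sse <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * cross_r
  sse <- pmax(sse, 0)                            # guard float cancellation
  r2 <- 1 - sse / ssx                            # ssx recycles down rows
  r2[ssx == 0, ] <- 0
  vals <- array(0, dim = c(3, n1, n2),
                dimnames = list(c("MI", "R2", "PCC"), sc$cell_ids, st$spot_ids))
  vals[1, , ] <- mi; vals[2, , ] <- r2; vals[3, , ] <- pcc
  structure(list(values = vals, metric_names = c("MI", "R2", "PCC"),
                 cell_ids = sc$cell_ids, spot_ids = st$spot_ids,
                 rho2_clamp = MI_RHO2_EPS),
            class = "CorrelationTensor")
}

#' @export
print.CorrelationTensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("CorrelationTensor: 3 metrics (MI, R2, PCC) x %d cells x %d spots\n",
              d[2], d[3]))
  invisible(x)
}
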