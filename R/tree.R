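# Weighted regression tree on binary mask features: the LIME surrogate.
# Splits maximize the weighted sum-of-squares reduction; the depth cap plays
# the role of the complexity penalty. Importances are the classic
# impurity-decrease totals per feature. Deterministic: ties break on the
# lowest feature index.

wsse <- function(y, w) {
  sw <- sum(w)
  if (sw <= 0) return(0)
  mu <- sum(w * y) / sw
  sum(w * (y - mu)^2)
}

fit_wtree_node <- function(X, y, w, depth, max_depth, min_obs, imp_env) {
  sw <- sum(w)
  mu <- if (sw > 0) sum(w * y) / sw else 0
  node_sse <- wsse(y, w)
  if (depth >= max_depth || length(y) < min_obs || node_sse <= 1e-15)
    return(list(leaf = TRUE, value = mu))
  best <- list(gain = 0, feature = NA_integer_)
  for (f in seq_len(ncol(X))) {
    left <- X[, f] == 0
    if (!any(left) || all(left)) next
    gain <- node_sse - wsse(y[left], w[left]) - wsse(y[!left], w[!left])
    if (gain > best$gain + 1e-15) best <- list(gain = gain, feature = f)
  }
  if (is.na(best$feature)) return(list(leaf = TRUE, value = mu))
  imp_env$importance[best$feature] <- imp_env$importance[best$feature] + best$gain
  left <- X[, best$feature] == 0
  list(leaf = FALSE, feature = best$feature, value = mu,
       left = fit_wtree_node(X[left, , drop = FALSE], y[left], w[left],
                             depth + 1, max_depth, min_obs, imp_env),
       right = fit_wtree_node(X[!left, , drop = FALSE], y[!left], w[!left],
                              depth + 1, max_depth, min_obs, imp_env))
}

# Fit; returns list(tree, importance) with importance of length ncol(X).
fit_wtree <- function(X, y, w = rep(1, length(y)), max_depth = 3L,
                      min_obs = 2L) {
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  env <- new.env()
  env$importance <- numeric(ncol(X))
  tree <- fit_wtree_node(X, y, w, 0L, max_depth, min_obs, env)
  list(tree = tree, importance = env$importance)
}

predict_wtree_one <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] == 0) node$left else node$right
  node$value
}

predict_wtree <- function(fit, X) {
  apply(X, 1, function(x) predict_wtree_one(fit$tree, x))
}
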