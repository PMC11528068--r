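#' Classifier configuration
#'
#' Holds the training hyperparameters. The `resnet50` architecture keeps the
#' reference defaults (learning rate 0.00005, momentum 0.8, weight decay
#' 0.0125, 100 epochs); the `small-cnn` test profile, whose learning rate is
#' otherwise unspecified, resolves it to 0.01 so it can train at desk scale.
#'
#' @param architecture `"resnet50"` (default) or `"small-cnn"`.
#' @param epochs number of passes over the training set.
#' @param learning_rate SGD step size; `NULL` resolves per architecture.
#' @param momentum SGD momentum factor.
#' @param weight_decay L2 penalty applied to convolution and dense weights.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and shuffling.
#' @param heads 1 for a single cell-type label, 2 for a stage x type
#'   multilabel model (shared trunk, one softmax head per label).
#' @return `ClassifierConfig` list.
#' @export
classifier_config <- function(architecture = c("resnet50", "small-cnn"),
                              epochs = 100L, learning_rate = NULL,
                              momentum = 0.8, weight_decay = 0.0125,
                              batch_size = 32L, seed = 0L, heads = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(learning_rate))
    learning_rate <- if (architecture == "resnet50") 5e-5 else 0.01
  stopifnot(epochs >= 1, learning_rate > 0, momentum >= 0, weight_decay >= 0,
            batch_size >= 1, heads %in% c(1L, 2L))
  structure(list(architecture = architecture, epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), heads = as.integer(heads)),
            class = "ClassifierConfig")
}

as_label_frame <- function(labels, heads) {
  if (is.data.frame(labels)) lf <- labels
  else lf <- data.frame(label = labels, stringsAsFactors = FALSE)
  if (ncol(lf) < heads) stop_sf("need ", heads, " label columns")
  lf[seq_len(heads)]
}

#' Stratified train/test split of labeled cells
#'
#' Splits cell ids stratified by the (joint) label so per-class proportions
#' are preserved; disjoint, exhaustive, reproducible under the seed.
#'
#' @param labels named vector, or data.frame with rownames = cell ids and one
#'   or two label columns (stratification uses the joint label).
#' @param train_frac fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_frac = 0.7, seed = 0L) {
  if (is.data.frame(labels)) {
    ids <- rownames(labels)
    joint <- interaction(labels, drop = TRUE)
  } else {
    ids <- names(labels)
    joint <- factor(labels)
  }
  if (is.null(ids)) stop_sf("labels must carry cell ids (names or rownames)")
  if (train_frac <= 0 || train_frac >= 1)
    stop_sf("train_frac must lie strictly in (0, 1)")
  sizes <- table(joint)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons))
    stop_sf("classes with a single cell cannot be split: ",
            paste(singletons, collapse = ", "))
  withr::with_seed(seed, {
    train <- character(0)
    for (cl in levels(joint)) {
      members <- ids[joint == cl]
      n_tr <- clamp(round(train_frac * length(members)), 1, length(members) - 1)
      train <- c(train, sample(members, n_tr))
    }
    train
  }) -> train
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

encode_onehot <- function(fac) {
  q <- nlevels(fac)
  oh <- matrix(0, q, length(fac))
  oh[cbind(as.integer(fac), seq_along(fac))] <- 1
  oh
}

#' Train the pseudo-image CNN classifier
#'
#' Stochastic gradient descent with momentum and L2 weight decay; batch
#' normalization in the convolution blocks; He initialization; softmax
#' cross-entropy per head (summed for the two-head multilabel model). All
#' randomness (initialization, shuffling) is governed by `cfg$seed`.
#'
#' @param images `H x W x 3 x n` array (e.g. `render_images()$images`), or a
#'   list of `PseudoImage`s.
#' @param labels factor/character vector of length n (1 head), or a
#'   data.frame with one column per head; ids in names/rownames optional.
#' @param cfg a [classifier_config()].
#' @return `TrainedClassifier`: trunk + head layers, per-head `class_names`,
#'   the config, and a per-epoch `history` (loss, training accuracy).
#' @export
train_classifier <- function(images, labels, cfg = classifier_config("small-cnn",
                                                                     epochs = 30L)) {
  X <- stack_images(images)
  d <- dim(X)
  n <- d[4]
  lf <- as_label_frame(labels, cfg$heads)
  if (nrow(lf) != n) stop_sf("labels and images differ in length")
  facs <- lapply(lf, function(col) factor(as.character(col)))
  for (f in facs) if (nlevels(f) < 2)
    stop_sf("need at least 2 classes per label head")
  onehots <- lapply(facs, encode_onehot)

  withr::with_seed(cfg$seed, {
    trunk <- switch(cfg$architecture,
                    "small-cnn" = build_small_cnn_trunk(d[3]),
                    "resnet50" = build_resnet50_trunk(d[3]))
    feat_dim <- trunk_out_dim(trunk, d[1:3])
    heads <- lapply(facs, function(f) nn_dense(feat_dim, nlevels(f)))
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          train_accuracy = numeric(0))
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        nb <- length(idx)
        xb <- X[, , , idx, drop = FALSE]
        ft <- forward_layers(trunk, xb, training = TRUE)
        trunk <- ft$layers
        feat <- ft$out
        dfeat <- 0
        hit <- rep(TRUE, nb)
        for (h in seq_along(heads)) {
          fh <- dense_forward(heads[[h]], feat)
          probs <- softmax_cols(fh$out)
          yb <- onehots[[h]][, idx, drop = FALSE]
          ep_loss <- ep_loss - sum(log(pmax(colSums(probs * yb), 1e-12)))
          hit <- hit & (max.col(t(probs)) == max.col(t(yb)))
          dlogit <- (probs - yb) / nb
          bh <- dense_backward(heads[[h]], fh$cache, dlogit)
          heads[[h]] <- sgd_update_layer(heads[[h]], bh$grads, cfg$learning_rate,
                                         cfg$momentum, cfg$weight_decay)
          dfeat <- dfeat + bh$dx
        }
        ep_hits <- ep_hits + sum(hit)
        bt <- backward_layers(trunk, ft$caches, dfeat)
        trunk <- sgd_update(trunk, bt$grads, cfg$learning_rate, cfg$momentum,
                            cfg$weight_decay)
        if (!is.finite(ep_loss))
          stop_sf("non-finite training loss at epoch ", epoch,
                  "; reduce the learning rate")
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / n,
                                           train_accuracy = ep_hits / n))
    }
    list(trunk = trunk, heads = heads, history = history)
  }) -> fit

  structure(list(trunk = fit$trunk, heads = fit$heads,
                 class_names = lapply(facs, levels), cfg = cfg,
                 input_dim = d[1:3], history = fit$history),
            class = "TrainedClassifier")
}

stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (inherits(images, "PseudoImage")) images <- list(images)
  if (is.list(images) && !is.null(images$images)) return(images$images)
  if (is.list(images) && all(vapply(images, inherits, TRUE, "PseudoImage"))) {
    d <- dim(images[[1]]$channels)
    X <- array(0, c(d, length(images)))
    for (i in seq_along(images)) X[, , , i] <- images[[i]]$channels
    return(X)
  }
  stop_sf("images must be an H x W x 3 x n array or a list of PseudoImages")
}

#' Predict class score vectors
#'
#' Forward pass in evaluation mode (batch-norm running moments). Scores per
#' head lie on the simplex. `clf` may also be a plain function mapping an
#' image batch array to a score matrix (used by the attribution module for
#' oracle models).
#'
#' @param clf a `TrainedClassifier` or `function(images) -> n x q matrix`.
#' @param images image array/list as in [train_classifier()].
#' @param batch_size forward-pass chunk size.
#' @return `n x q` score matrix (1 head) or list of such matrices (2 heads).
#' @export
predict_scores <- function(clf, images, batch_size = 256L) {
  X <- stack_images(images)
  if (is.function(clf)) return(clf(X))
  stopifnot(inherits(clf, "TrainedClassifier"))
  if (!identical(dim(X)[1:3], as.integer(clf$input_dim)) &&
      !all(dim(X)[1:3] == clf$input_dim))
    stop_sf("image shape does not match the training shape")
  n <- dim(X)[4]
  outs <- lapply(clf$class_names, function(cn)
    matrix(0, n, length(cn), dimnames = list(NULL, cn)))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- X[, , , idx, drop = FALSE]
    feat <- forward_layers(clf$trunk, xb, training = FALSE)$out
    for (h in seq_along(clf$heads)) {
      probs <- softmax_cols(dense_forward(clf$heads[[h]], feat)$out)
      outs[[h]][idx, ] <- t(probs)
    }
  }
  if (length(outs) == 1) outs[[1]] else outs
}

#' Predict hard class labels (argmax per head)
#'
#' @inheritParams predict_scores
#' @return character vector (1 head) or data.frame (2 heads).
#' @export
predict_classes <- function(clf, images) {
  sc <- predict_scores(clf, images)
  pick <- function(s) colnames(s)[max.col(s, ties.method = "first")]
  if (is.matrix(sc)) return(pick(sc))
  as.data.frame(lapply(sc, pick), col.names = paste0("head", seq_along(sc)))
}

#' Classification accuracy
#'
#' `mode = "single"`: fraction of matching labels. `mode = "exact-match"`:
#' for multilabel predictions, the fraction of cells whose labels are
#' correct on every head. A per-class confusion matrix (joint labels for
#' exact-match) is attached as attribute `"confusion"`.
#'
#' @param pred,truth vectors, or data.frames with one column per head.
#' @param mode `"single"` or `"exact-match"`.
#' @return scalar in \[0, 1\] with attribute `confusion`.
#' @export
accuracy_score <- function(pred, truth, mode = c("single", "exact-match")) {
  mode <- match.arg(mode)
  if (mode == "single") {
    pred <- as.character(unlist(pred, use.names = FALSE))
    truth <- as.character(unlist(truth, use.names = FALSE))
  } else {
    pred <- apply(as.data.frame(pred), 1, paste, collapse = "|")
    truth <- apply(as.data.frame(truth), 1, paste, collapse = "|")
  }
  if (!length(pred)) stop_sf("empty input")
  if (length(pred) != length(truth)) stop_sf("length mismatch")
  acc <- mean(pred == truth)
  attr(acc, "confusion") <- table(truth = truth, pred = pred)
  acc
}
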