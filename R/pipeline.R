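# End-to-end orchestration: simulate (or load) -> preprocess -> correlate ->
# image -> train -> attribute -> deconvolve -> evaluate -> ICC/enrichment,
# with a JSON manifest recording parameters, seeds, stage wall times and
# content hashes of every written file.

#' Build a run configuration
#'
#' Every stochastic stage carries an explicit seed (derived from `seed` when
#' not given). The config is serialized verbatim into the output directory.
#'
#' @param out_dir output directory.
#' @param sim a [synthetic_config()] describing the fixture (or `NULL` with
#'   `input_paths` naming sc/st/coords/labels files to load instead).
#' @param input_paths optional named list/vector with `sc`, `st`, `coords`,
#'   `labels` paths.
#' @param raster `c(H, W)` or `NULL` to infer from the spot layout.
#' @param classifier a [classifier_config()].
#' @param train_frac train fraction of the stratified split.
#' @param lime list of attribution options: `n_samples`, `K`, `per_type`
#'   (cells explained per type), `seed`.
#' @param fuse `"minmax"` or `"raw"` tensor fusion before deconvolution.
#' @param top_frac high-attribution fraction.
#' @param seed master seed; also used for the split.
#' @return `RunConfig` list.
#' @export
run_config <- function(out_dir,
                       sim = synthetic_config(),
                       input_paths = NULL,
                       raster = NULL,
                       classifier = classifier_config("small-cnn", epochs = 30L),
                       train_frac = 0.7,
                       lime = list(n_samples = 200L, K = 40L, per_type = 5L,
                                   seed = NULL),
                       fuse = "minmax",
                       top_frac = 0.2,
                       seed = 0L) {
  if (is.null(seed) || is.null(classifier$seed))
    stop_sf("every stochastic stage needs an explicit seed")
  lime$n_samples <- lime$n_samples %||% 200L
  lime$K <- lime$K %||% 40L
  lime$per_type <- lime$per_type %||% 5L
  lime$seed <- lime$seed %||% (seed + 2L)
  if (!is.null(sim) && is.null(sim$seed))
    stop_sf("simulation stage needs an explicit seed")
  structure(list(out_dir = out_dir, sim = sim, input_paths = input_paths,
                 raster = raster, classifier = classifier,
                 train_frac = train_frac, lime = lime, fuse = fuse,
                 top_frac = top_frac, seed = as.integer(seed)),
            class = "RunConfig")
}

# Serialize a matrix with its dimnames; deterministic text output.
write_named_matrix <- function(m, path) {
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

#' Run the whole workflow from one configuration
#'
#' Executes every stage on the configured fixture, writes all stage outputs
#' under `cfg$out_dir`, and returns (and writes) a manifest listing stage
#' order, parameters, seeds, wall times, output hashes and summary
#' statistics (test accuracy, per-type deconvolution metrics, ARI between
#' the predominant-type partition and the ground-truth predominant types,
#' ICC matrix path). Any stage failure stops with an error naming the
#' stage; deterministic stages are hash-stable across reruns.
#'
#' @param cfg a [run_config()].
#' @return the manifest list, invisibly.
#' @export
run_end_to_end <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "spotfuse",
                   seed = cfg$seed,
                   stages = list(), summary = list(), outputs = list())
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop_sf("stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  data <- stage("input", function() {
    if (!is.null(cfg$input_paths)) {
      ip <- cfg$input_paths
      c(load_paired_dataset(ip[["sc"]], ip[["st"]], ip[["coords"]],
                            ip[["labels"]]), list(truth = NULL))
    } else {
      sim <- simulate_paired(cfg$sim)
      write_fixture(sim, file.path(cfg$out_dir, "fixture"))
      list(sc = sim$sc, st = sim$st, truth = sim$truth)
    }
  })

  pp <- stage("preprocess", function()
    filter_and_align(data$sc, data$st))

  tensor <- stage("correlate", function() {
    tn <- build_tensor(pp$sc, pp$st)
    for (i in 1:3) {
      lay <- tn$values[i, , ]
      write_named_matrix(lay, file.path(cfg$out_dir,
                                        paste0("tensor_", tn$metric_names[i],
                                               ".csv")))
    }
    tn
  })

  imaging <- stage("image", function() {
    map <- build_pixel_map(pp$st$coords,
                           H = cfg$raster[1] %||% NULL,
                           W = cfg$raster[2] %||% NULL)
    utils::write.table(map$pixel_of_spot,
                       file.path(cfg$out_dir, "pixel_map.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    render_images(tensor, map)
  })

  clf_res <- stage("train", function() {
    labels <- stats::setNames(pp$sc$labels$cell_type, pp$sc$cell_ids)
    split <- split_train_test(labels, cfg$train_frac, seed = cfg$seed)
    tri <- match(split$train, imaging$cell_ids)
    tei <- match(split$test, imaging$cell_ids)
    clf <- train_classifier(imaging$images[, , , tri, drop = FALSE],
                            labels[split$train], cfg$classifier)
    pred <- predict_classes(clf, imaging$images[, , , tei, drop = FALSE])
    acc <- accuracy_score(pred, labels[split$test])
    utils::write.table(data.frame(cell_id = split$test, predicted = pred,
                                  truth = labels[split$test]),
                       file.path(cfg$out_dir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(clf = clf, split = split, accuracy = as.numeric(acc),
         labels = labels)
  })

  attrib <- stage("attribute", function() {
    seg <- segment_superpixels(imaging$map,
                               K = min(cfg$lime$K,
                                       nrow(spot_pixels(imaging$map))))
    labels <- clf_res$labels
    types <- sort(unique(labels))
    sel_ids <- unlist(lapply(types, function(t)
      utils::head(names(labels)[labels == t], cfg$lime$per_type)))
    maps <- list(); map_labels <- character(0)
    for (id in sel_ids) {
      i <- match(id, imaging$cell_ids)
      img <- structure(list(channels = imaging$images[, , , i],
                            cell_id = id, mask = imaging$mask),
                       class = "PseudoImage")
      maps[[id]] <- explain_image(clf_res$clf, img, seg,
                                  target = unname(labels[id]),
                                  n_samples = cfg$lime$n_samples,
                                  seed = cfg$lime$seed)
      map_labels <- c(map_labels, labels[id])
    }
    byt <- aggregate_by_type(maps, map_labels)
    for (t in names(byt))
      write_named_matrix(byt[[t]]$values,
                         file.path(cfg$out_dir, paste0("attribution_", t, ".csv")))
    list(seg = seg, by_type = byt)
  })

  decon <- stage("deconvolve", function() {
    props <- deconvolve(tensor, clf_res$labels, fuse = cfg$fuse)
    write_named_matrix(props$values, file.path(cfg$out_dir, "proportions.csv"))
    props
  })

  eval_res <- stage("evaluate", function() {
    if (is.null(data$truth)) return(NULL)
    res <- evaluate_deconvolution(decon, data$truth$values)
    utils::write.table(res, file.path(cfg$out_dir, "deconvolution_metrics.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    truth_pred <- colnames(data$truth$values)[apply(data$truth$values, 1,
                                                    which.max)]
    list(metrics = res,
         ari = ari(decon$predominant, truth_pred))
  })

  icc_res <- stage("icc", function() {
    if (length(attrib$by_type) < 2) return(NULL)
    icc <- icc_matrix(attrib$by_type, imaging$map)
    write_named_matrix(icc$icc, file.path(cfg$out_dir, "icc.csv"))
    icc
  })

  outputs <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% c("manifest.json")]
  manifest$outputs <- stats::setNames(
    lapply(outputs, file_hash),
    sub(paste0("^", cfg$out_dir, "/?"), "", outputs))
  manifest$summary <- list(
    n_cells = nrow(pp$sc$values), n_spots = nrow(pp$st$values),
    n_genes = ncol(pp$sc$values),
    accuracy = clf_res$accuracy,
    per_type_pcc = if (!is.null(eval_res))
      stats::setNames(eval_res$metrics$PCC, eval_res$metrics$type) else NULL,
    ari = if (!is.null(eval_res)) eval_res$ari else NULL,
    icc_path = if (!is.null(icc_res)) "icc.csv" else NULL)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
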