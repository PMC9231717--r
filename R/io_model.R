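# Text-based model persistence ------------------------------------------------
#
# A model directory holds JSON only: config, trained parameters, batch-norm
# running statistics, the decision cutoff, the training log and the aligned
# gene-universe order. Graph operators are rebuilt from the GMT + edge list
# at load time, so the directory stays small and human-inspectable.

pack_tree <- function(x) {
  if (is.list(x)) return(lapply(x, pack_tree))
  list(.dim = if (is.null(dim(x))) length(x) else dim(x),
       .val = as.numeric(x))
}

# inverse of pack_tree on JSON parsed with simplifyVector = FALSE
unpack_tree <- function(x) {
  if (is.list(x) && !is.null(x[[".val"]])) {
    v <- as.numeric(unlist(x[[".val"]]))
    d <- as.integer(unlist(x[[".dim"]]))
    if (length(d) > 1) dim(v) <- d
    return(v)
  }
  lapply(x, unpack_tree)
}

#' Save a trained model to a directory of JSON files
#'
#' @param fit A `trained_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_trained_model <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA)
  wj(unclass(fit$config), "config.json")
  wj(pack_tree(fit$model$params), "weights.json")
  wj(pack_tree(fit$model$stats), "bn_stats.json")
  wj(list(cutoff = fit$cutoff, class_names = fit$class_names,
          best_epoch = fit$best_epoch, training_log = fit$training_log,
          class_weights = fit$class_weights,
          gene_ids = fit$model$gene_ids,
          pathway_ids = unname(fit$model$ops$pathway_ids)), "meta.json")
  invisible(dir)
}

#' Load a trained model saved by [save_trained_model()]
#'
#' @param dir Model directory.
#' @param graphs The pathway graphs the model was trained with (rebuilt from
#'   the same GMT + edge list; pathway order and the gene universe are
#'   checked against the stored metadata).
#' @return A `trained_model`.
#' @export
load_trained_model <- function(dir, graphs) {
  rj <- function(f) jsonlite::read_json(file.path(dir, f),
                                        simplifyVector = TRUE)
  cfg_raw <- rj("config.json")
  cfg <- do.call(model_config, cfg_raw)
  meta <- rj("meta.json")
  model <- build_model(graphs, as.character(meta$gene_ids), cfg)
  if (!identical(unname(model$ops$pathway_ids),
                 as.character(meta$pathway_ids))) {
    stop("pathway order of the supplied graphs differs from the saved model")
  }
  weights <- jsonlite::read_json(file.path(dir, "weights.json"),
                                 simplifyVector = FALSE)
  stats <- jsonlite::read_json(file.path(dir, "bn_stats.json"),
                               simplifyVector = FALSE)
  model$params <- unpack_tree(weights)
  model$stats <- unpack_tree(stats)
  structure(list(model = model, config = cfg, cutoff = meta$cutoff,
                 training_log = meta$training_log,
                 best_epoch = meta$best_epoch,
                 class_weights = meta$class_weights,
                 class_names = as.character(meta$class_names)),
            class = "trained_model")
}

#' Write an importance table as TSV (`rank`, `id`, `mean_abs_shap`)
#' @param x An `importance_table`.
#' @param path Output path.
#' @export
write_importance_tsv <- function(x, path) {
  write.table(x$entries[, c("rank", "id", "mean_abs_shap")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
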