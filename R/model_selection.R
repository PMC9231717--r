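# Hyperparameter search, cross-validation, cutoff and metrics ----------------

#' Stratified k-fold assignment
#'
#' Samples of each class are shuffled and dealt round-robin into folds, so
#' folds partition the data and class proportions are preserved as closely as
#' the counts allow.
#'
#' @param labels Factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate one configuration
#'
#' Stratified k-fold: each fold is held out once, the model is trained on the
#' remainder (fold validation loss drives early stopping), Youden's cutoff is
#' chosen on the training part, and metrics are computed on the held-out
#' fold.
#'
#' @param ds Aligned `expression_dataset`.
#' @param graphs Pathway graphs.
#' @param config A [model_config()].
#' @param k Folds (default 5).
#' @param fold_seed Seed for the fold assignment (the model seed lives in
#'   `config`).
#' @return A `cv_result`: `config`, `fold_metrics` (data.frame),
#'   `mean_metrics`.
#' @export
cross_validate <- function(ds, graphs, config, k = 5, fold_seed = config$seed) {
  fold <- stratified_folds(ds$labels, k, fold_seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    va_idx <- which(fold == f)
    tr <- subset_dataset(ds, tr_idx)
    va <- subset_dataset(ds, va_idx)
    fit <- train_model(tr, graphs, config, val = va)
    pred <- predict_class(fit, va)
    m <- compute_metrics(pred, va$labels, positive_class = ds$class_names[2])
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1)
  }
  fm <- do.call(rbind, rows)
  structure(list(config = config, fold_metrics = fm,
                 mean_metrics = colMeans(fm[, -1])),
            class = "cv_result")
}

#' Subset an expression dataset by sample index
#' @param ds An `expression_dataset`.
#' @param idx Integer sample indices.
#' @export
subset_dataset <- function(ds, idx) {
  expression_dataset(ds$values[idx, , drop = FALSE],
                     as.character(ds$labels)[idx], ds$class_names)
}

#' Random hyperparameter search with cross-validation
#'
#' Draws `n_draws` configurations uniformly from `search_space` and evaluates
#' each by stratified k-fold CV. The winner is the highest mean validation
#' accuracy; ties break by higher mean F1, then by lower parameter count.
#'
#' @param ds Aligned `expression_dataset`.
#' @param graphs Pathway graphs.
#' @param search_space Named list; each element is the vector of candidate
#'   values for one [model_config()] argument (e.g.
#'   `list(hidden_channels = c(4, 8, 16), learning_rate = c(1e-3, 1e-2))`).
#' @param n_draws Number of configurations to draw.
#' @param seed Seed for the draw sequence and fold assignment.
#' @param base_config Config supplying every argument not in the space.
#' @param k CV folds.
#' @return List with `best_config`, `best_cv`, and `results` (all
#'   `cv_result`s).
#' @export
random_search <- function(ds, graphs, search_space, n_draws = 10, seed = 1,
                          base_config = model_config(), k = 5) {
  if (length(search_space) == 0) stop("empty search space")
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) {
    cfg <- unclass(base_config)
    for (nm in names(search_space)) {
      cand <- search_space[[nm]]
      pick <- if (is.list(cand)) cand[[sample.int(length(cand), 1)]] else
        cand[[sample.int(length(cand), 1)]]
      cfg[[nm]] <- pick
    }
    do.call(model_config, cfg[setdiff(names(cfg), character(0))])
  })
  results <- lapply(draws, function(cfg) {
    cross_validate(ds, graphs, cfg, k = k, fold_seed = seed)
  })
  acc <- vapply(results, function(r) r$mean_metrics[["accuracy"]], numeric(1))
  f1 <- vapply(results, function(r) r$mean_metrics[["f1"]], numeric(1))
  np <- vapply(draws, function(cfg) {
    count_params(build_model(graphs, ds$gene_ids, cfg))
  }, numeric(1))
  ord <- order(-acc, -f1, np)
  best <- ord[1]
  list(best_config = draws[[best]], best_cv = results[[best]],
       results = results)
}

#' Youden-index cutoff from training scores
#'
#' Scans the finite candidate set of observed scores (plus `+Inf`, the
#' predict-none threshold) under the convention `score >= t` predicts the
#' positive class, and returns the candidate maximizing Youden's J
#' (sensitivity + specificity - 1). Ties break toward the candidate closest
#' to 0.5. Degenerate situations (best J <= 0, or all scores equal) warn.
#'
#' @param scores Positive-class probabilities.
#' @param labels Factor with two levels; second level is the positive class.
#' @return The selected threshold.
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present to select a cutoff")
  }
  pos <- labels == levels(labels)[2]
  cand <- c(sort(unique(scores)), Inf)
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    sens + spec - 1
  }, numeric(1))
  best_j <- max(j)
  ties <- which(j >= best_j - 1e-12)
  pick <- ties[which.min(abs(cand[ties] - 0.5))]
  if (best_j <= 0) {
    warning("Youden's index is not positive at any threshold (J = ",
            signif(best_j, 3), "); degenerate cutoff returned")
  }
  if (length(unique(scores)) == 1) {
    warning("all scores identical; cutoff equals the common score")
    return(scores[1])
  }
  cand[pick]
}

#' Binary classification metrics
#'
#' One-vs-rest binary metrics with an explicit positive class: precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 their harmonic mean, accuracy
#' `(TP+TN)/total`. Ratios with zero denominators are reported as 0 and
#' flagged in `undefined`.
#'
#' @param predictions Factor/character of predicted labels.
#' @param labels True labels.
#' @param positive_class Label treated as positive.
#' @return A `metric_report` list: `accuracy`, `precision`, `recall`, `f1`,
#'   `confusion` (2x2 matrix, predicted x truth), `positive_class`,
#'   `undefined` (character vector of flagged ratios).
#' @export
compute_metrics <- function(predictions, labels, positive_class) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  pp <- predictions == positive_class
  lp <- labels == positive_class
  tp <- sum(pp & lp); fp <- sum(pp & !lp)
  fn <- sum(!pp & lp); tn <- sum(!pp & !lp)
  undefined <- character(0)
  prec <- if (tp + fp == 0) { undefined <- c(undefined, "precision"); 0 } else
    tp / (tp + fp)
  rec <- if (tp + fn == 0) { undefined <- c(undefined, "recall"); 0 } else
    tp / (tp + fn)
  f1 <- if (prec + rec == 0) { undefined <- c(undefined, "f1"); 0 } else
    2 * prec * rec / (prec + rec)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(predicted = c("pos", "neg"),
                                 truth = c("pos", "neg")))
  structure(list(accuracy = (tp + tn) / length(labels), precision = prec,
                 recall = rec, f1 = f1, confusion = conf,
                 positive_class = positive_class, undefined = undefined),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f (positive: %s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$positive_class))
  invisible(x)
}
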