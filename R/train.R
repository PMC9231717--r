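# Training loop ---------------------------------------------------------------

#' Inverse-frequency class weights, normalized to mean 1
#' @param labels Factor with two levels.
#' @return Length-2 numeric vector in level order.
#' @export
class_weights <- function(labels) {
  n <- table(labels)
  if (any(n == 0)) stop("both classes must be present")
  w <- sum(n) / (2 * as.numeric(n))
  w / mean(w)
}

#' Train a classifier
#'
#' Minibatch Adam on the weighted cross-entropy with L2 penalty. After each
#' epoch the monitored loss (validation loss when `val` is given, otherwise
#' the full-training-set loss, both in eval mode) is checked by the
#' early-stopping monitor; the parameters of the best epoch are restored.
#' Fully reproducible given `config$seed`.
#'
#' @param ds Training `expression_dataset`, aligned to the graph universe.
#' @param graphs Named list of `pathway_graph` objects.
#' @param config A [model_config()].
#' @param val Optional validation `expression_dataset` monitored for early
#'   stopping.
#' @param select_cutoff_on_train If `TRUE` (default) the decision cutoff is
#'   chosen by Youden's index on the training scores, else fixed at 0.5.
#' @return A `trained_model`: list with `model`, `config`, `cutoff`,
#'   `training_log` (per-epoch monitored loss), `best_epoch`,
#'   `class_weights`.
#' @export
train_model <- function(ds, graphs, config, val = NULL,
                        select_cutoff_on_train = TRUE) {
  y <- as.integer(ds$labels)
  if (any(table(ds$labels) < 2)) stop("need at least 2 samples per class")
  model <- build_model(graphs, ds$gene_ids, config)   # seeds RNG internally
  cw <- class_weights(ds$labels)
  X <- ds$values
  n <- nrow(X)
  opt <- adam_init(model$params)
  monitor <- early_stop_new(config$patience)
  log_loss <- numeric(0)
  best_params <- model$params
  best_stats <- model$stats

  eval_loss <- function(model, Xe, ye) {
    fw <- model_forward(model, Xe, training = FALSE)
    weighted_cross_entropy(fw$probs, ye, cw, config$l2_lambda,
                           penalized_weights(model$params))
  }

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- model_forward(model, Xb, training = TRUE)
      model$stats <- fw$stats
      dlogits <- ce_logit_grad(fw$probs, yb, cw)
      bw <- model_backward(model, dlogits, fw$caches)
      grads <- bw$grads
      if (config$l2_lambda > 0) {
        add_l2 <- function(g, w) g + 2 * config$l2_lambda * w
        for (nm in intersect(c("W0", "W1"), names(grads))) {
          grads[[nm]] <- add_l2(grads[[nm]], model$params[[nm]])
        }
        grads$head$W <- Map(add_l2, grads$head$W, model$params$head$W)
      }
      st <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- st$params
      opt <- st$state
    }
    mon_loss <- if (is.null(val)) {
      eval_loss(model, X, y)
    } else {
      eval_loss(model, val$values, as.integer(val$labels))
    }
    log_loss <- c(log_loss, mon_loss)
    monitor <- early_stop_update(monitor, mon_loss)
    if (monitor$improved) {
      best_params <- model$params
      best_stats <- model$stats
    }
    if (monitor$stop) break
  }
  model$params <- best_params
  model$stats <- best_stats

  cutoff <- 0.5
  if (select_cutoff_on_train) {
    scores <- predict_proba(model, X)
    cutoff <- suppressWarnings(select_cutoff(scores, ds$labels))
  }
  structure(list(model = model, config = config, cutoff = cutoff,
                 training_log = log_loss, best_epoch = monitor$best_epoch,
                 class_weights = cw,
                 class_names = ds$class_names),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(paste0("trained %s model: %d epochs run, best epoch %d, ",
                     "cutoff %.3f\n"),
              toupper(x$model$arch), length(x$training_log), x$best_epoch,
              x$cutoff))
  invisible(x)
}

#' Positive-class probability scores
#'
#' @param model A `gcn_model` or `trained_model`.
#' @param X Aligned samples x genes matrix (or `expression_dataset`).
#' @return Numeric vector: probability of the positive class (second class
#'   level) per sample.
#' @export
predict_proba <- function(model, X) {
  if (inherits(model, "trained_model")) model <- model$model
  if (inherits(X, "expression_dataset")) X <- X$values
  model_forward(model, X, training = FALSE)$probs[, 2]
}

#' Class predictions at the stored cutoff
#'
#' Scores at or above the cutoff predict the positive class.
#'
#' @param fit A `trained_model`.
#' @param X Aligned matrix or `expression_dataset`.
#' @return Factor of predicted labels with the training class levels.
#' @export
predict_class <- function(fit, X) {
  p <- predict_proba(fit, X)
  factor(fit$class_names[1 + (p >= fit$cutoff)], levels = fit$class_names)
}

#' Build an untrained baseline model
#'
#' Dispatches on `config$arch`: `"mlp"` consumes the raw aligned gene vector
#' through three fully connected layers; `"gcn_mlp"` keeps the graph
#' convolution trunk and replaces the single linear head with the same
#' three-layer stack; `"gcn"` returns the plain model.
#'
#' @inheritParams build_model
#' @return An untrained `gcn_model`.
#' @export
build_baseline <- function(graphs, gene_ids, config) {
  build_model(graphs, gene_ids, config)
}
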