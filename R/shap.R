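# Shapley-value attribution ---------------------------------------------------
#
# The explained quantity is the pre-softmax logit margin
#   f(x) = logit(class1) - logit(class0),
# not the probability. For the plain GCN the head is a single linear layer,
# so the margin is exactly linear in the pooled features and pathway-level
# Shapley values have the closed form
#   phi_i = w_i * (z_i - mean background z_i),
# which satisfies local accuracy exactly. For nonlinear heads (GCN-MLP) a
# seeded permutation-sampling estimator is used. Gene-level attribution uses
# expected gradients (integrated gradients averaged over background samples);
# since the eval-mode network is piecewise linear in its input, a modest
# number of path steps already gives tight local accuracy.

margin_weights <- function(fit) {
  model <- if (inherits(fit, "trained_model")) fit$model else fit
  if (model$arch != "gcn") stop("linear-head margin weights require arch 'gcn'")
  W <- model$params$head$W[[1]]
  b <- model$params$head$b[[1]]
  list(w = W[, 2] - W[, 1], b = b[2] - b[1])
}

head_margin <- function(fit, pooled) {
  model <- if (inherits(fit, "trained_model")) fit$model else fit
  ff <- fc_forward(pooled, model$params$head, model$stats$head,
                   model$config$dropout_rate, training = FALSE)
  ff$logits[, 2] - ff$logits[, 1]
}

#' Pooled activations for a dataset
#' @param fit `trained_model` or `gcn_model` with a graph trunk.
#' @param X Aligned matrix or `expression_dataset`.
#' @return Samples x (K * pool_channels) matrix.
#' @export
pooled_activations <- function(fit, X) {
  model <- if (inherits(fit, "trained_model")) fit$model else fit
  if (inherits(X, "expression_dataset")) X <- X$values
  if (model$arch == "mlp") stop("the MLP baseline has no pooling layer")
  model_forward(model, X, training = FALSE)$pooled
}

#' Shapley values at the pooling layer
#'
#' Attributes the logit margin of each sample to the K*pool_channels pooled
#' features. With the plain GCN's linear head the values are exact; with the
#' GCN-MLP head they are estimated by permutation sampling against the
#' background (seeded, `n_perm` permutations).
#'
#' @param fit A `trained_model` with a graph trunk.
#' @param ds Aligned `expression_dataset` (or matrix) to explain.
#' @param background_size Number of background samples (rows of `ds`) the
#'   reference distribution is built from; defaults to all samples, capped at
#'   1000.
#' @param n_perm Permutations for the sampled estimator (nonlinear heads).
#' @param seed Seed for background subsampling and permutation draws.
#' @return List: `values` (samples x features signed Shapley values),
#'   `base` (expected margin over the background), `margin` (per-sample
#'   margin), `feature_pathway` (pathway id per pooled feature).
#' @export
shap_pooling <- function(fit, ds, background_size = NULL, n_perm = 64,
                         seed = 1) {
  model <- fit$model
  X <- if (inherits(ds, "expression_dataset")) ds$values else ds
  Z <- pooled_activations(fit, X)
  n <- nrow(Z)
  if (is.null(background_size)) background_size <- min(n, 1000)
  if (background_size > n) {
    stop("background_size (", background_size, ") exceeds the number of samples (",
         n, ")")
  }
  set.seed(seed)
  bg_idx <- if (background_size < n) sample.int(n, background_size) else
    seq_len(n)
  Zbg <- Z[bg_idx, , drop = FALSE]
  margin <- head_margin(fit, Z)
  K <- model$ops$K
  p <- model$config$pool_channels
  feature_pathway <- rep(model$ops$pathway_ids, each = p)

  if (model$arch == "gcn") {
    mw <- margin_weights(fit)
    zbar <- colMeans(Zbg)
    values <- t((t(Z) - zbar) * mw$w)
    base <- sum(mw$w * zbar) + mw$b
  } else {
    # permutation-sampling Shapley against background rows
    nf <- ncol(Z)
    values <- matrix(0, n, nf)
    base <- mean(head_margin(fit, Zbg))
    for (i in seq_len(n)) {
      phi <- numeric(nf)
      for (r in seq_len(n_perm)) {
        ord <- sample.int(nf)
        bg <- Zbg[sample.int(nrow(Zbg), 1), ]
        cur <- bg
        prev_val <- head_margin(fit, matrix(cur, 1))
        for (ffeat in ord) {
          cur[ffeat] <- Z[i, ffeat]
          new_val <- head_margin(fit, matrix(cur, 1))
          phi[ffeat] <- phi[ffeat] + (new_val - prev_val)
          prev_val <- new_val
        }
      }
      values[i, ] <- phi / n_perm
    }
  }
  list(values = values, base = base, margin = margin,
       feature_pathway = feature_pathway)
}

#' Aggregate pooled Shapley values to pathway importance
#'
#' Per pathway, the mean of absolute Shapley values over its pool channels
#' and all samples; pathways are ranked in descending importance (ties keep
#' the original pathway order, stable).
#'
#' @param shap Result of [shap_pooling()].
#' @return An `importance_table`: data.frame `entries` with `id`,
#'   `mean_abs_shap`, `rank`; plus `level = "pathway"` and the per-sample
#'   signed value matrix.
#' @export
aggregate_pathway_importance <- function(shap) {
  ids <- unique(shap$feature_pathway)
  imp <- vapply(ids, function(k) {
    mean(abs(shap$values[, shap$feature_pathway == k, drop = FALSE]))
  }, numeric(1))
  ord <- order(-imp)   # stable: ties keep original pathway order
  entries <- data.frame(id = ids[ord], mean_abs_shap = unname(imp[ord]),
                        rank = seq_along(ids), stringsAsFactors = FALSE)
  structure(list(level = "pathway", entries = entries,
                 per_sample_values = shap$values,
                 feature_pathway = shap$feature_pathway),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("importance_table (%s level), top entries:\n", x$level))
  print(head(x$entries, 5), row.names = FALSE)
  invisible(x)
}

#' Gene-level Shapley values by expected gradients
#'
#' Integrated gradients of the logit margin along straight paths from
#' background samples to each explained sample, averaged over a seeded
#' background subset (the expected-gradients estimator). Per-gene importance
#' is the mean absolute attribution across samples.
#'
#' @param fit A `trained_model`.
#' @param ds Aligned `expression_dataset` to explain.
#' @param background_size Background rows drawn from `ds` (default
#'   `min(n, 16)`).
#' @param n_steps Path steps per background (midpoint rule, default 16).
#' @param seed Seed for the background draw.
#' @return An `importance_table` at gene level, with `local_accuracy`: the
#'   mean absolute completeness error relative to the mean absolute margin.
#' @export
shap_genes <- function(fit, ds, background_size = NULL, n_steps = 16,
                       seed = 1) {
  model <- fit$model
  X <- if (inherits(ds, "expression_dataset")) ds$values else ds
  n <- nrow(X)
  set.seed(seed)
  if (is.null(background_size)) background_size <- min(n, 16)
  if (background_size > n) stop("background_size exceeds the number of samples")
  bg_idx <- if (background_size < n) sample.int(n, background_size) else
    seq_len(n)
  values <- matrix(0, n, ncol(X))
  margin_of <- function(M) {
    fw <- model_forward(model, M, training = FALSE)
    fw$logits[, 2] - fw$logits[, 1]
  }
  for (b in bg_idx) {
    B <- matrix(X[b, ], n, ncol(X), byrow = TRUE)
    D <- X - B
    acc <- matrix(0, n, ncol(X))
    for (s in seq_len(n_steps)) {
      alpha <- (s - 0.5) / n_steps
      acc <- acc + margin_input_gradient(model, B + alpha * D)
    }
    values <- values + D * (acc / n_steps)
  }
  values <- values / length(bg_idx)
  margin <- margin_of(X)
  base <- mean(margin_of(X[bg_idx, , drop = FALSE]))
  completeness_err <- rowSums(values) + base - margin
  la <- mean(abs(completeness_err)) / max(mean(abs(margin)), 1e-12)
  imp <- colMeans(abs(values))
  ord <- order(-imp)
  entries <- data.frame(id = colnames(X)[ord], mean_abs_shap = unname(imp[ord]),
                        rank = seq_along(imp), stringsAsFactors = FALSE)
  structure(list(level = "gene", entries = entries,
                 per_sample_values = values, base = base, margin = margin,
                 local_accuracy = la),
            class = "importance_table")
}

#' Compare an importance ranking with an enrichment ranking
#'
#' Takes the top `top_n` pathways of the Shapley ranking and of the
#' enrichment ranking (by absolute NES) over a shared universe, and reports
#' the overlap plus Spearman correlation of the full rankings.
#'
#' @param table_a An `importance_table` at pathway level.
#' @param enrichment data.frame from [permutation_stats()].
#' @param top_n Size of the compared top lists.
#' @return List: `top_shap`, `top_gsea`, `overlap` (character vector),
#'   `n_overlap`, `spearman`.
#' @export
compare_rankings <- function(table_a, enrichment, top_n = 5) {
  ids_a <- table_a$entries$id
  ids_b <- enrichment$pathway_id
  universe <- intersect(ids_a, ids_b)
  if (length(universe) == 0) stop("no shared pathways between the rankings")
  if (top_n > length(universe)) {
    warning("top_n exceeds the shared universe; clipped to ", length(universe))
    top_n <- length(universe)
  }
  ea <- table_a$entries[table_a$entries$id %in% universe, ]
  eb <- enrichment[enrichment$pathway_id %in% universe, ]
  eb <- eb[order(-abs(eb$nes)), ]
  top_shap <- head(ea$id, top_n)
  top_gsea <- head(eb$pathway_id, top_n)
  rank_a <- match(universe, ea$id)
  rank_b <- match(universe, eb$pathway_id)
  list(top_shap = top_shap, top_gsea = top_gsea,
       overlap = intersect(top_shap, top_gsea),
       n_overlap = length(intersect(top_shap, top_gsea)),
       spearman = suppressWarnings(cor(rank_a, rank_b, method = "spearman")))
}
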