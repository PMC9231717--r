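# Rank-windowed logistic-regression validation --------------------------------
#
# If an importance ranking is meaningful, classifiers built from genes near
# the top of the ranking should beat classifiers built from genes near the
# bottom. Windows of consecutive ranks (5 pathways or 100 genes by default)
# are turned into L2-regularized logistic regressions, each evaluated on a
# held-out test set, and the F1-vs-window trend is summarized by an OLS
# slope.

#' Select gene windows along an importance ranking
#'
#' Pathway mode: consecutive non-overlapping blocks of `window_size`
#' pathways by rank; each window's genes are the deduplicated union of the
#' member genes (a gene shared by two pathways inside a window counts once;
#' a gene may reappear in a later window since windows are independent
#' models). Gene mode: consecutive blocks of `window_size` genes by rank.
#'
#' @param importance An `importance_table` (level must match `mode`).
#' @param sets A [gene_set_collection()] (pathway mode only).
#' @param mode `"pathways"` or `"genes"`.
#' @param window_size Ranks per window (5 pathways / 100 genes in the
#'   reference workflow).
#' @return List of character vectors of genes, one per window, in rank
#'   order. The last window carries the remainder.
#' @export
select_gene_windows <- function(importance, sets = NULL,
                                mode = c("pathways", "genes"),
                                window_size = if (match.arg(mode) == "pathways") 5 else 100) {
  mode <- match.arg(mode)
  ids <- importance$entries$id    # already in rank order
  if (mode == "pathways") {
    if (importance$level != "pathway") {
      stop("pathway mode needs a pathway-level importance table")
    }
    if (is.null(sets)) stop("pathway mode needs the gene_set_collection")
    n <- length(ids)
    if (window_size > n) {
      warning("window_size exceeds the number of pathways; one clipped window")
      window_size <- n
    }
    starts <- seq(1, n, by = window_size)
    lapply(starts, function(s) {
      block <- ids[s:min(s + window_size - 1, n)]
      unique(unlist(sets$sets[block], use.names = FALSE))
    })
  } else {
    if (importance$level != "gene") {
      stop("gene mode needs a gene-level importance table")
    }
    n <- length(ids)
    if (window_size > n) {
      warning("window_size exceeds the number of genes; one clipped window")
      window_size <- n
    }
    starts <- seq(1, n, by = window_size)
    lapply(starts, function(s) ids[s:min(s + window_size - 1, n)])
  }
}

#' Fit and evaluate one window's logistic regression
#'
#' Ridge (L2) logistic regression on the training samples restricted to
#' `genes`, with class-balanced sample weights, evaluated on the test set at
#' the 0.5 probability cutoff.
#'
#' @param ds_train,ds_test Aligned `expression_dataset`s sharing the gene
#'   universe.
#' @param genes Character vector of explanatory genes.
#' @param l2_c Inverse regularization strength (ridge penalty is
#'   `1 / (l2_c * n_train)` on the glmnet scale); default 1.
#' @param seed Seed (the fit is deterministic; kept for interface
#'   stability).
#' @return A `metric_report` on the test set, with attribute `n_genes`.
#' @export
fit_window_classifier <- function(ds_train, ds_test, genes, l2_c = 1,
                                  seed = 1) {
  genes <- intersect(genes, ds_train$gene_ids)
  if (length(genes) == 0) stop("no window gene is present in the universe")
  Xtr <- ds_train$values[, genes, drop = FALSE]
  Xte <- ds_test$values[, genes, drop = FALSE]
  if (all(Xtr == 0)) stop("all-zero feature submatrix for this window")
  set.seed(seed)
  y <- as.integer(ds_train$labels) - 1L
  w <- class_weights(ds_train$labels)[as.integer(ds_train$labels)]
  lambda <- 1 / (l2_c * nrow(Xtr))
  if (length(genes) == 1) {
    # glmnet needs >= 2 columns; duplicate and halve the coefficient load
    Xtr <- cbind(Xtr, Xtr)
    Xte <- cbind(Xte, Xte)
  }
  fit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                        lambda = lambda, weights = w, standardize = FALSE)
  p <- as.vector(predict(fit, Xte, type = "response"))
  pred <- factor(ds_test$class_names[1 + (p >= 0.5)],
                 levels = ds_test$class_names)
  m <- compute_metrics(pred, ds_test$labels,
                       positive_class = ds_test$class_names[2])
  attr(m, "n_genes") <- length(unique(genes))
  m
}

#' Run the full rank-window validation
#'
#' @inheritParams fit_window_classifier
#' @param importance An `importance_table`.
#' @param sets Gene sets (pathway mode).
#' @param mode `"pathways"` or `"genes"`.
#' @param window_size Ranks per window.
#' @return A `rank_window_result` data.frame: `window_index`, `n_genes`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
rank_window_validation <- function(importance, sets, ds_train, ds_test,
                                   mode = c("pathways", "genes"),
                                   window_size = NULL, l2_c = 1, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(window_size)) window_size <- if (mode == "pathways") 5 else 100
  windows <- select_gene_windows(importance, sets, mode, window_size)
  rows <- lapply(seq_along(windows), function(i) {
    m <- fit_window_classifier(ds_train, ds_test, windows[[i]], l2_c, seed)
    data.frame(window_index = i, n_genes = attr(m, "n_genes"),
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rank_window_result", "data.frame")
  out
}

#' Performance-vs-rank trend
#'
#' OLS slope of F1 against window index (negative slope = performance decays
#' down the importance ranking), plus the per-window table.
#'
#' @param results A `rank_window_result` (>= 2 windows).
#' @return List: `slope`, `intercept`, `table`.
#' @export
trend_report <- function(results) {
  if (nrow(results) < 2) stop("need at least 2 windows for a trend")
  fit <- lm(f1 ~ window_index, data = results)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       table = as.data.frame(results))
}
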