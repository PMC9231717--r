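# GCN over pathway graphs -----------------------------------------------------
#
# Architecture (shared weights across all K pathway graphs):
#   per-node expression (1 channel)
#     -> graph conv 1 (width h) -> ReLU -> batch norm -> dropout
#     -> graph conv 2 (width p = pool_channels) -> ReLU -> batch norm -> dropout
#     -> per-graph average pooling (p values per pathway, K*p total)
#     -> fully connected head -> softmax.
# The plain GCN head is a single linear layer; the GCN-MLP head has three
# linear layers (ReLU + batch norm + dropout after the first two); the MLP
# baseline applies the same three-layer stack directly to the aligned gene
# vector. All K graphs are assembled once into a block-diagonal normalized
# adjacency, so a minibatch is a single sparse-dense product.

#' Model configuration
#'
#' @param hidden_channels Width of the first graph-convolution layer.
#' @param pool_channels Width of the second layer = values per pathway after
#'   average pooling (default 10).
#' @param dropout_rate Dropout probability after each conv / hidden linear
#'   layer.
#' @param l2_lambda L2 penalty on connection weights (batch-norm parameters
#'   and biases excluded).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience (consecutive non-improving
#'   epochs).
#' @param seed Integer seed driving initialization, dropout and shuffling.
#' @param arch `"gcn"`, `"mlp"` or `"gcn_mlp"`.
#' @param mlp_hidden Hidden widths of the two hidden linear layers used by
#'   the MLP and GCN-MLP heads.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_channels = 8, pool_channels = 10,
                         dropout_rate = 0.2, l2_lambda = 1e-4,
                         learning_rate = 0.01, batch_size = 32,
                         max_epochs = 100, patience = 5, seed = 1,
                         arch = c("gcn", "mlp", "gcn_mlp"),
                         mlp_hidden = c(64, 16)) {
  arch <- match.arg(arch)
  stopifnot(pool_channels >= 1, patience >= 1, hidden_channels >= 1,
            dropout_rate >= 0, dropout_rate < 1, l2_lambda >= 0,
            learning_rate > 0, length(mlp_hidden) == 2)
  structure(list(hidden_channels = hidden_channels,
                 pool_channels = pool_channels,
                 dropout_rate = dropout_rate, l2_lambda = l2_lambda,
                 learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed), arch = arch,
                 mlp_hidden = mlp_hidden),
            class = "model_config")
}

# Static operators shared by all samples: block-diagonal normalized
# adjacency, node -> gene index into the aligned universe, and the K x M
# averaging matrix for pooling.
build_gcn_operators <- function(graphs, gene_ids) {
  pathway_ids <- vapply(graphs, `[[`, character(1), "pathway_id")
  sizes <- vapply(graphs, function(g) length(g$nodes), integer(1))
  node_gene_idx <- unlist(lapply(graphs, function(g) match(g$nodes, gene_ids)),
                          use.names = FALSE)
  if (anyNA(node_gene_idx)) {
    missing <- unique(unlist(lapply(graphs, function(g)
      setdiff(g$nodes, gene_ids))))
    stop("graph genes absent from the aligned universe: ",
         paste(head(missing, 5), collapse = ", "))
  }
  M <- sum(sizes)
  K <- length(graphs)
  Sblock <- Matrix::bdiag(lapply(graphs, `[[`, "norm_adjacency"))
  Sblock <- methods::as(Sblock, "CsparseMatrix")
  graph_of_node <- rep(seq_len(K), sizes)
  Pool <- Matrix::sparseMatrix(i = graph_of_node, j = seq_len(M),
                               x = 1 / sizes[graph_of_node],
                               dims = c(K, M))
  list(pathway_ids = pathway_ids, sizes = sizes,
       node_gene_idx = node_gene_idx, M = M, K = K,
       Sblock = Sblock, Pool = Pool)
}

#' Build an untrained model
#'
#' @param graphs Named list of `pathway_graph` objects (ignored for
#'   `arch = "mlp"`, but kept for the shared interface).
#' @param gene_ids Aligned gene universe (model input order).
#' @param config A [model_config()].
#' @return An object of class `gcn_model` holding operators, parameters and
#'   batch-norm statistics. Weights are initialized from the config seed.
#' @export
build_model <- function(graphs, gene_ids, config) {
  set.seed(config$seed)
  ops <- build_gcn_operators(graphs, gene_ids)
  h <- config$hidden_channels
  p <- config$pool_channels
  params <- list()
  stats <- list()
  if (config$arch %in% c("gcn", "gcn_mlp")) {
    params$W0 <- glorot_init(1, h)
    params$W1 <- glorot_init(h, p)
    bn1 <- bn_params(h); bn2 <- bn_params(p)
    params$bn1_gamma <- bn1$gamma; params$bn1_beta <- bn1$beta
    params$bn2_gamma <- bn2$gamma; params$bn2_beta <- bn2$beta
    stats$bn1 <- bn_stats(h); stats$bn2 <- bn_stats(p)
    head_in <- ops$K * p
  } else {
    head_in <- length(gene_ids)
  }
  head_dims <- if (config$arch == "gcn") {
    c(head_in, 2)
  } else {
    c(head_in, config$mlp_hidden, 2)
  }
  params$head <- fc_init(head_dims)
  stats$head <- fc_stats_init(head_dims)
  structure(list(arch = config$arch, config = config, ops = ops,
                 gene_ids = gene_ids, params = params, stats = stats),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("%s model: %d pathway graphs, %d genes, %d trainable parameters\n",
              toupper(x$arch), x$ops$K, length(x$gene_ids), count_params(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Connection weights, biases and batch-norm scale/shift; running batch-norm
#' statistics are not trainable and are excluded.
#'
#' @param model A `gcn_model`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  n <- 0L
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  as.integer(cnt(model$params))
}

# One graph-convolution application on a single graph: sigma(S H W).
#' Apply one graph-convolution layer
#'
#' Computes `sigma(S %*% H %*% W)` with `S` the graph's normalized adjacency
#' and `sigma` either ReLU or the identity.
#'
#' @param g A `pathway_graph`.
#' @param H Node-feature matrix, `N_k` x `c_in`.
#' @param W Weight matrix, `c_in` x `c_out`.
#' @param activation If `TRUE` apply ReLU.
#' @return `N_k` x `c_out` matrix.
#' @export
graph_conv_layer <- function(g, H, W, activation = TRUE) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (nrow(H) != length(g$nodes)) stop("H must have one row per node")
  if (ncol(H) != nrow(W)) stop("dimension mismatch between H and W")
  Z <- as.matrix(g$norm_adjacency %*% H %*% W)
  if (activation) relu(Z) else Z
}

# Trunk forward: X is samples x genes (aligned). Channel activations are kept
# as (M*S) x channels matrices, one column per channel.
trunk_forward <- function(model, X, training) {
  ops <- model$ops
  S <- nrow(X)
  H0 <- t(X[, ops$node_gene_idx, drop = FALSE])            # M x S
  P <- as.matrix(ops$Sblock %*% H0)                        # M x S
  Pvec <- as.vector(P)
  Z1 <- outer(Pvec, as.vector(model$params$W0))            # (M*S) x h
  R1 <- relu(Z1)
  bf1 <- bn_forward(R1, model$params$bn1_gamma, model$params$bn1_beta,
                    model$stats$bn1, training)
  model$stats$bn1 <- bf1$stats
  dp1 <- dropout_forward(bf1$y, model$config$dropout_rate, training)
  D1 <- dp1$y
  h <- ncol(Z1)
  Tm <- matrix(0, nrow(Z1), h)
  for (j in seq_len(h)) {
    Tm[, j] <- as.vector(ops$Sblock %*% matrix(D1[, j], ops$M, S))
  }
  Z2 <- Tm %*% model$params$W1                             # (M*S) x p
  R2 <- relu(Z2)
  bf2 <- bn_forward(R2, model$params$bn2_gamma, model$params$bn2_beta,
                    model$stats$bn2, training)
  model$stats$bn2 <- bf2$stats
  dp2 <- dropout_forward(bf2$y, model$config$dropout_rate, training)
  D2 <- dp2$y
  p <- ncol(Z2)
  pooled <- matrix(0, S, ops$K * p)
  for (cc in seq_len(p)) {
    PC <- as.matrix(ops$Pool %*% matrix(D2[, cc], ops$M, S))  # K x S
    pooled[, seq(cc, by = p, length.out = ops$K)] <- t(PC)
  }
  cache <- list(S = S, Pvec = Pvec, Z1 = Z1, bn1 = bf1$cache, mask1 = dp1$mask,
                Tm = Tm, Z2 = Z2, bn2 = bf2$cache, mask2 = dp2$mask)
  list(pooled = pooled, cache = cache, stats = model$stats)
}

trunk_backward <- function(model, dpooled, cache, want_input_grad = FALSE) {
  ops <- model$ops
  S <- cache$S
  p <- ncol(model$params$W1)
  h <- ncol(model$params$W0)
  dD2 <- matrix(0, ops$M * S, p)
  for (cc in seq_len(p)) {
    dPC <- t(dpooled[, seq(cc, by = p, length.out = ops$K), drop = FALSE])
    dD2[, cc] <- as.vector(Matrix::crossprod(ops$Pool, dPC))
  }
  dB2 <- dropout_backward(dD2, cache$mask2)
  bb2 <- bn_backward(dB2, model$params$bn2_gamma, cache$bn2)
  dZ2 <- bb2$dx * (cache$Z2 > 0)
  gW1 <- crossprod(cache$Tm, dZ2)
  dTm <- dZ2 %*% t(model$params$W1)
  dD1 <- matrix(0, ops$M * S, h)
  for (j in seq_len(h)) {
    dD1[, j] <- as.vector(ops$Sblock %*% matrix(dTm[, j], ops$M, S))
  }
  dB1 <- dropout_backward(dD1, cache$mask1)
  bb1 <- bn_backward(dB1, model$params$bn1_gamma, cache$bn1)
  dZ1 <- bb1$dx * (cache$Z1 > 0)
  gW0 <- matrix(colSums(dZ1 * cache$Pvec), 1, h)
  grads <- list(W0 = gW0, W1 = gW1,
                bn1_gamma = bb1$dgamma, bn1_beta = bb1$dbeta,
                bn2_gamma = bb2$dgamma, bn2_beta = bb2$dbeta)
  dX <- NULL
  if (want_input_grad) {
    dPvec <- as.vector(dZ1 %*% t(model$params$W0))
    dH0 <- as.matrix(ops$Sblock %*% matrix(dPvec, ops$M, S))   # M x S
    agg <- rowsum(dH0, group = ops$node_gene_idx)              # genes hit x S
    dX <- matrix(0, S, length(model$gene_ids))
    dX[, as.integer(rownames(agg))] <- t(agg)
  }
  list(grads = grads, dX = dX)
}

#' Forward pass
#'
#' @param model A `gcn_model`.
#' @param X Samples x genes matrix aligned to `model$gene_ids` (a single
#'   vector is treated as one sample).
#' @param training Train mode (batch statistics + dropout) or eval mode.
#' @return List with `logits`, `probs` (samples x 2, rows sum to 1), `pooled`
#'   (samples x K*pool_channels; `NULL` for the MLP), `caches`, and updated
#'   batch-norm `stats`.
#' @export
model_forward <- function(model, X, training = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$gene_ids)) {
    stop("input has ", ncol(X), " genes but the model expects ",
         length(model$gene_ids), " (align to the universe first)")
  }
  pooled <- NULL; trunk_cache <- NULL
  if (model$arch %in% c("gcn", "gcn_mlp")) {
    tf <- trunk_forward(model, X, training)
    model$stats$bn1 <- tf$stats$bn1
    model$stats$bn2 <- tf$stats$bn2
    pooled <- tf$pooled
    trunk_cache <- tf$cache
    head_in <- pooled
  } else {
    head_in <- X
  }
  ff <- fc_forward(head_in, model$params$head, model$stats$head,
                   model$config$dropout_rate, training)
  model$stats$head <- ff$stats
  probs <- softmax_rows(ff$logits)
  list(logits = ff$logits, probs = probs, pooled = pooled,
       caches = list(trunk = trunk_cache, head = ff$caches),
       stats = model$stats)
}

# Full backward pass given dlogits; returns grads in the shape of
# model$params (plus dX when requested).
model_backward <- function(model, dlogits, caches, want_input_grad = FALSE) {
  hb <- fc_backward(dlogits, model$params$head, caches$head)
  grads <- list(head = hb$grads)
  dX <- NULL
  if (model$arch %in% c("gcn", "gcn_mlp")) {
    tb <- trunk_backward(model, hb$dx, caches$trunk, want_input_grad)
    grads <- c(tb$grads, grads)
    dX <- tb$dX
  } else if (want_input_grad) {
    dX <- hb$dx
  }
  list(grads = grads, dX = dX)
}

# connection weights entering the L2 penalty (no biases, no batch norm)
penalized_weights <- function(params) {
  c(Filter(Negate(is.null), params[c("W0", "W1")]), params$head$W)
}

#' Gradient of the positive-class logit margin with respect to the input
#'
#' Evaluates, in eval mode, `d(logit[class1] - logit[class0]) / dX` for each
#' row of `X`. Used by the gradient-based gene-level Shapley estimator.
#'
#' @param model A trained `gcn_model`.
#' @param X Samples x genes aligned matrix.
#' @return Matrix of the same shape as `X`.
#' @export
margin_input_gradient <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  fw <- model_forward(model, X, training = FALSE)
  dlogits <- matrix(rep(c(-1, 1), each = nrow(X)), nrow(X), 2)
  model_backward(model, dlogits, fw$caches, want_input_grad = TRUE)$dX
}
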