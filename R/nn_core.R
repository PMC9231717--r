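# Minimal neural-network primitives ------------------------------------------
#
# Hand-rolled dense/graph layers sized for pathway-scale problems: everything
# is plain matrix algebra on doubles, trained by Adam on CPU. Batch
# normalization is column-wise (one statistic per feature/channel); dropout is
# "inverted" (activations rescaled by 1/(1-p) at train time, identity at
# evaluation). All randomness flows from R's global RNG so a single
# `set.seed()` makes training fully reproducible.

relu <- function(x) pmax(x, 0)

glorot_init <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# --- batch normalization (column-wise over an n x F matrix) ------------------

bn_params <- function(n_features) {
  list(gamma = rep(1, n_features), beta = rep(0, n_features))
}

bn_stats <- function(n_features) {
  list(rm = rep(0, n_features), rv = rep(1, n_features))
}

bn_forward <- function(x, gamma, beta, stats, training,
                       momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- t(t(x) - mu)
    v <- colMeans(xc * xc)
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- t(t(xc) * inv_sd)
    y <- t(t(xhat) * gamma + beta)
    stats$rm <- (1 - momentum) * stats$rm + momentum * mu
    stats$rv <- (1 - momentum) * stats$rv + momentum * v
    list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, training = TRUE),
         stats = stats)
  } else {
    inv_sd <- 1 / sqrt(stats$rv + eps)
    y <- t((t(x) - stats$rm) * inv_sd * gamma + beta)
    list(y = y, cache = list(inv_sd = inv_sd, training = FALSE), stats = stats)
  }
}

bn_backward <- function(dy, gamma, cache) {
  if (cache$training) {
    n <- nrow(dy)
    xhat <- cache$xhat
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    dxhat <- t(t(dy) * gamma)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    # dx = inv_sd/n * (n*dxhat - s1 - xhat*s2), column-wise
    dx <- t((t(dxhat) - s1 / n - t(xhat) * (s2 / n)) * cache$inv_sd)
    list(dx = dx, dgamma = dgamma, dbeta = dbeta)
  } else {
    list(dx = t(t(dy) * (gamma * cache$inv_sd)),
         dgamma = colSums(dy) * 0, dbeta = colSums(dy) * 0)
  }
}

# --- dropout -----------------------------------------------------------------

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- matrix((runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# --- fully connected stack ---------------------------------------------------
#
# L linear layers; after every layer except the last: ReLU, batch norm,
# dropout. The last layer emits raw logits (softmax is applied in the loss).

fc_init <- function(dims) {
  L <- length(dims) - 1
  W <- vector("list", L); b <- vector("list", L)
  gamma <- vector("list", max(L - 1, 0)); beta <- gamma
  for (i in seq_len(L)) {
    W[[i]] <- glorot_init(dims[i], dims[i + 1])
    b[[i]] <- rep(0, dims[i + 1])
    if (i < L) {
      p <- bn_params(dims[i + 1])
      gamma[[i]] <- p$gamma; beta[[i]] <- p$beta
    }
  }
  list(W = W, b = b, gamma = gamma, beta = beta)
}

fc_stats_init <- function(dims) {
  L <- length(dims) - 1
  lapply(seq_len(max(L - 1, 0)), function(i) bn_stats(dims[i + 1]))
}

fc_forward <- function(x, params, stats, dropout_rate, training) {
  L <- length(params$W)
  caches <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    z <- h %*% params$W[[i]] + rep(params$b[[i]], each = nrow(h))
    cache <- list(input = h, z = NULL)
    if (i < L) {
      r <- relu(z)
      bf <- bn_forward(r, params$gamma[[i]], params$beta[[i]], stats[[i]],
                       training)
      stats[[i]] <- bf$stats
      dp <- dropout_forward(bf$y, dropout_rate, training)
      cache$z <- z
      cache$bn <- bf$cache
      cache$mask <- dp$mask
      h <- dp$y
    } else {
      h <- z
    }
    caches[[i]] <- cache
  }
  list(logits = h, caches = caches, stats = stats)
}

fc_backward <- function(dlogits, params, caches) {
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  ggamma <- vector("list", max(L - 1, 0)); gbeta <- ggamma
  dh <- dlogits
  for (i in rev(seq_len(L))) {
    cache <- caches[[i]]
    if (i < L) {
      dh <- dropout_backward(dh, cache$mask)
      bb <- bn_backward(dh, params$gamma[[i]], cache$bn)
      ggamma[[i]] <- bb$dgamma; gbeta[[i]] <- bb$dbeta
      dh <- bb$dx * (cache$z > 0)
    }
    gW[[i]] <- crossprod(cache$input, dh)
    gb[[i]] <- colSums(dh)
    dh <- dh %*% t(params$W[[i]])
  }
  list(grads = list(W = gW, b = gb, gamma = ggamma, beta = gbeta), dx = dh)
}

# --- softmax / weighted cross-entropy ---------------------------------------

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Weighted cross-entropy with L2 penalty
#'
#' Mean over samples of `w_class * (-log p_true)` plus
#' `l2_lambda * sum(W^2)` over the connection weights supplied in
#' `weight_matrices` (batch-norm parameters and biases are excluded by the
#' caller).
#'
#' @param probs Samples x 2 matrix of class probabilities.
#' @param y Integer vector in `{1, 2}` (true class index).
#' @param class_weights Length-2 positive weights, one per class.
#' @param l2_lambda Nonnegative L2 coefficient.
#' @param weight_matrices List of numeric arrays entering the penalty.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, y, class_weights = c(1, 1),
                                   l2_lambda = 0, weight_matrices = list()) {
  p_true <- probs[cbind(seq_along(y), y)]
  nll <- -log(pmax(p_true, 1e-12))
  data_term <- mean(class_weights[y] * nll)
  pen <- if (l2_lambda > 0) {
    l2_lambda * sum(vapply(weight_matrices, function(w) sum(w * w), numeric(1)))
  } else 0
  data_term + pen
}

# gradient of the data term wrt logits (softmax + weighted NLL, mean-reduced)
ce_logit_grad <- function(probs, y, class_weights) {
  n <- nrow(probs)
  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), y)] <- 1
  (probs - onehot) * (class_weights[y] / n)
}

# --- Adam over nested parameter lists ---------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    attributes(out) <- attributes(a)
    out
  } else {
    f(a)
  }
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# --- early stopping ----------------------------------------------------------

#' Early-stopping monitor
#'
#' Tracks the best (lowest) monitored loss; training stops once the loss has
#' failed to improve on `patience` consecutive epochs, and the parameters
#' from the best epoch are restored by the caller.
#'
#' @param patience Number of consecutive non-improving epochs tolerated.
#' @return A monitor state; update it with [early_stop_update()].
#' @export
early_stop_new <- function(patience = 5) {
  list(patience = patience, best = Inf, best_epoch = 0L,
       bad_epochs = 0L, epoch = 0L, stop = FALSE)
}

#' @rdname early_stop_new
#' @param state A monitor state from [early_stop_new()].
#' @param loss Monitored loss for the epoch just finished.
#' @return Updated state with fields `stop` (stop now?), `improved`,
#'   `best_epoch`.
#' @export
early_stop_update <- function(state, loss) {
  state$epoch <- state$epoch + 1L
  if (is.na(loss) || !is.finite(loss)) {
    stop("monitored loss is not finite at epoch ", state$epoch,
         " (divergent training)")
  }
  if (loss < state$best) {
    state$best <- loss
    state$best_epoch <- state$epoch
    state$bad_epochs <- 0L
    state$improved <- TRUE
  } else {
    state$bad_epochs <- state$bad_epochs + 1L
    state$improved <- FALSE
  }
  state$stop <- state$bad_epochs >= state$patience
  state
}
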