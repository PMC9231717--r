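test_that("graph_conv_layer matches hand computations", {
  iso <- build_graph("i", "G1")
  expect_equal(graph_conv_layer(iso, matrix(-2), matrix(1)), matrix(0))
  expect_equal(graph_conv_layer(iso, matrix(3), matrix(1)), matrix(3))
  # two-node edge: S = 0.5 * ones, H = (1,3), W = 1, no activation -> (2,2)
  g2 <- build_graph("e", c("A", "B"), rbind(c("A", "B")))
  expect_equal(graph_conv_layer(g2, matrix(c(1, 3)), matrix(1), activation = FALSE),
               matrix(c(2, 2)), ignore_attr = TRUE)
  expect_equal(graph_conv_layer(g2, matrix(rnorm(2)), matrix(0)),
               matrix(c(0, 0)), ignore_attr = TRUE)
  expect_error(graph_conv_layer(g2, matrix(1, 2, 2), matrix(1, 3, 1)),
               "dimension mismatch")
})

test_that("forward: pooled width is K * pool_channels and probabilities sum to 1", {
  fx <- tiny_fixture()
  cfg <- model_config(hidden_channels = 3, pool_channels = 4, seed = 1)
  m <- build_model(fx$graphs, fx$train$gene_ids, cfg)
  fw <- model_forward(m, fx$train$values[1:7, ])
  expect_equal(ncol(fw$pooled), length(fx$graphs) * 4)
  expect_equal(rowSums(fw$probs), rep(1, 7), tolerance = 1e-12)
})

test_that("zero input with zero statistics and biases gives softmax of head bias", {
  fx <- tiny_fixture()
  cfg <- model_config(hidden_channels = 3, pool_channels = 2, seed = 2)
  m <- build_model(fx$graphs, fx$train$gene_ids, cfg)
  m$params$head$b[[1]] <- c(0.3, -0.2)
  x0 <- matrix(0, 1, length(fx$train$gene_ids))
  fw <- model_forward(m, x0, training = FALSE)
  # beta = 0, running mean 0: zero input stays zero through both conv blocks
  expect_equal(as.vector(fw$pooled), rep(0, ncol(fw$pooled)), tolerance = 1e-12)
  expect_equal(as.vector(fw$probs), as.vector(exp(c(0.3, -0.2)) / sum(exp(c(0.3, -0.2)))),
               tolerance = 1e-12)
})

test_that("forward is permutation-equivariant within a graph", {
  fx <- tiny_fixture(seed = 7)
  cfg <- model_config(hidden_channels = 4, pool_channels = 3, seed = 3)
  m <- build_model(fx$graphs, fx$train$gene_ids, cfg)
  X <- fx$train$values[1:4, ]
  p0 <- model_forward(m, X)$pooled
  # permute the node order of the first graph (and its adjacency) consistently
  g <- fx$graphs[[1]]
  perm <- sample(length(g$nodes))
  g2 <- g
  g2$nodes <- g$nodes[perm]
  g2$adjacency <- g$adjacency[perm, perm]
  g2$norm_adjacency <- g$norm_adjacency[perm, perm]
  graphs2 <- fx$graphs
  graphs2[[1]] <- g2
  m2 <- build_model(graphs2, fx$train$gene_ids, cfg)
  m2$params <- m$params
  m2$stats <- m$stats
  p2 <- model_forward(m2, X)$pooled
  expect_equal(p2, p0, tolerance = 1e-12)
})

test_that("parameter count grows in K only through the head", {
  cfg <- model_config(hidden_channels = 5, pool_channels = 10, seed = 1)
  counts <- sapply(c(3, 6, 12), function(K) {
    fx <- tiny_fixture(seed = 11, n_pathways = K)
    count_params(build_model(fx$graphs, fx$train$gene_ids, cfg))
  })
  # head adds K*pool_channels*2 weights; conv side is constant
  expect_equal(diff(counts), c(3 * 10 * 2, 6 * 10 * 2))
  fx <- tiny_fixture(seed = 11, n_pathways = 3)
  m <- build_model(fx$graphs, fx$train$gene_ids, cfg)
  conv_side <- 1 * 5 + 5 * 10 + 2 * 5 + 2 * 10   # W0, W1, bn scale/shift
  expect_equal(count_params(m), conv_side + 3 * 10 * 2 + 2)
})

test_that("MLP parameter count matches layer-shape arithmetic; dispatch works", {
  fx <- tiny_fixture(seed = 13)
  G <- length(fx$train$gene_ids)
  a <- 7; b <- 4
  cfg <- model_config(arch = "mlp", mlp_hidden = c(a, b), seed = 1)
  m <- build_baseline(fx$graphs, fx$train$gene_ids, cfg)
  expect_equal(m$arch, "mlp")
  bn_terms <- 2 * a + 2 * b
  expect_equal(count_params(m),
               G * a + a + a * b + b + b * 2 + 2 + bn_terms)
  expect_equal(build_model(fx$graphs, fx$train$gene_ids,
                           model_config(arch = "gcn", seed = 1))$arch, "gcn")
})

test_that("GCN-MLP shares the conv trunk: identical pooled output on identical weights", {
  fx <- tiny_fixture(seed = 17)
  cfg_g <- model_config(arch = "gcn", hidden_channels = 3, pool_channels = 2, seed = 5)
  cfg_m <- model_config(arch = "gcn_mlp", hidden_channels = 3, pool_channels = 2,
                        seed = 5, mlp_hidden = c(6, 3))
  mg <- build_model(fx$graphs, fx$train$gene_ids, cfg_g)
  mm <- build_model(fx$graphs, fx$train$gene_ids, cfg_m)
  for (nm in c("W0", "W1", "bn1_gamma", "bn1_beta", "bn2_gamma", "bn2_beta")) {
    mm$params[[nm]] <- mg$params[[nm]]
  }
  mm$stats$bn1 <- mg$stats$bn1; mm$stats$bn2 <- mg$stats$bn2
  X <- fx$train$values[1:5, ]
  expect_equal(model_forward(mm, X)$pooled, model_forward(mg, X)$pooled,
               tolerance = 1e-12)
})

test_that("weighted cross-entropy closed forms", {
  p <- rbind(c(0, 1))   # perfect prediction of class 2 (clipped internally)
  expect_equal(weighted_cross_entropy(p, 2L), 0, tolerance = 1e-10)
  expect_equal(weighted_cross_entropy(rbind(c(0.5, 0.5)), 1L), log(2))
  expect_equal(weighted_cross_entropy(rbind(c(0.5, 0.5)), 1L, c(2, 1)), 2 * log(2))
  # L2 term
  expect_equal(weighted_cross_entropy(rbind(c(0.5, 0.5)), 1L, c(1, 1),
                                      l2_lambda = 0.1,
                                      weight_matrices = list(matrix(2))),
               log(2) + 0.4)
  # balanced classes give equal weights
  expect_equal(class_weights(factor(c("a", "a", "b", "b"))), c(1, 1))
  expect_equal(class_weights(factor(c(rep("a", 3), "b"))), c(2 / 3, 2) / mean(c(2 / 3, 2)))
})

test_that("backprop matches finite differences (gcn, small instance)", {
  fx <- tiny_fixture(seed = 23, n_pathways = 4, n_per_class = 5,
                     genes_per_pathway = c(3, 5))
  cfg <- model_config(hidden_channels = 3, pool_channels = 2, seed = 31,
                      dropout_rate = 0, l2_lambda = 0)
  m <- build_model(fx$graphs, fx$train$gene_ids, cfg)
  X <- fx$train$values[1:6, ]
  y <- as.integer(fx$train$labels)[1:6]
  cw <- c(1.3, 0.7)
  fw <- model_forward(m, X, training = TRUE)
  bw <- model_backward(m, pathgcn:::ce_logit_grad(fw$probs, y, cw), fw$caches)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    weighted_cross_entropy(model_forward(m2, X, training = TRUE)$probs, y, cw)
  }
  eps <- 1e-5
  # probe a handful of coordinates in each parameter block
  for (nm in c("W0", "W1", "bn1_gamma", "bn2_beta")) {
    v <- m$params[[nm]]
    for (j in unique(round(seq(1, length(v), length.out = 3)))) {
      p1 <- m$params; p1[[nm]][j] <- p1[[nm]][j] + eps
      p2 <- m$params; p2[[nm]][j] <- p2[[nm]][j] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(bw$grads[[nm]][j], num, tolerance = 1e-5)
    }
  }
  hW <- m$params$head$W[[1]]
  j <- sample(length(hW), 3)
  for (jj in j) {
    p1 <- m$params; p1$head$W[[1]][jj] <- p1$head$W[[1]][jj] + eps
    p2 <- m$params; p2$head$W[[1]][jj] <- p2$head$W[[1]][jj] - eps
    expect_equal(bw$grads$head$W[[1]][jj],
                 (loss_at(p1) - loss_at(p2)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("early stopping follows the consecutive-non-improvement contract", {
  st <- early_stop_new(patience = 5)
  losses <- c(1.0, 0.9, 0.91, 0.92, 0.93, 0.94, 0.95)
  stopped_at <- NA
  for (i in seq_along(losses)) {
    st <- early_stop_update(st, losses[i])
    if (st$stop) { stopped_at <- i; break }
  }
  expect_equal(stopped_at, 7)          # 5 consecutive non-improvements
  expect_equal(st$best_epoch, 2L)      # restore epoch-2 weights
  # strictly decreasing: never stops
  st2 <- early_stop_new(5)
  for (l in seq(1, 0.1, by = -0.1)) st2 <- early_stop_update(st2, l)
  expect_false(st2$stop)
  expect_error(early_stop_update(early_stop_new(2), NaN), "divergent")
})

test_that("training is deterministic given the seed and learns a planted signal", {
  fx <- tiny_fixture(seed = 29, n_pathways = 6, n_per_class = 20)
  cfg <- model_config(hidden_channels = 4, pool_channels = 3, seed = 77,
                      max_epochs = 50, batch_size = 16, learning_rate = 0.02)
  f1 <- train_model(fx$train, fx$graphs, cfg)
  f2 <- train_model(fx$train, fx$graphs, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$training_log, f2$training_log)
  acc <- compute_metrics(predict_class(f1, fx$train), fx$train$labels,
                         "class1")$accuracy
  expect_gt(acc, 0.95)
})
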