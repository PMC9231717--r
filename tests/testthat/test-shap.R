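# Builds a small trained-ish GCN whose head weights we can set by hand.
shap_toy <- function(seed = 3, n_pathways = 3, pool_channels = 2,
                     n_per_class = 8) {
  fx <- tiny_fixture(seed = seed, n_pathways = n_pathways,
                     n_per_class = n_per_class)
  cfg <- model_config(hidden_channels = 3, pool_channels = pool_channels,
                      seed = seed)
  m <- build_model(fx$graphs, fx$train$gene_ids, cfg)
  fit <- structure(list(model = m, config = cfg, cutoff = 0.5,
                        class_names = fx$train$class_names),
                   class = "trained_model")
  list(fx = fx, fit = fit)
}

test_that("linear-head Shapley values follow the exact closed form", {
  toy <- shap_toy(n_pathways = 1, pool_channels = 2)
  fit <- toy$fit
  # force head margin weights w = (2, -1), zero bias
  fit$model$params$head$W[[1]] <- cbind(c(0, 0), c(2, -1))
  fit$model$params$head$b[[1]] <- c(0, 0)
  Z <- pooled_activations(fit, toy$fx$train)
  sh <- shap_pooling(fit, toy$fx$train)
  zbar <- colMeans(Z)
  expect_equal(sh$values, t((t(Z) - zbar) * c(2, -1)), tolerance = 1e-12)
  # the spec'd pointwise case: z=(1,1), background mean (0,0)
  phi <- c(2, -1) * (c(1, 1) - c(0, 0))
  expect_equal(phi, c(2, -1))
  # sample at the background mean gets zero attribution
  i <- 1
  ZA <- Z
  ZA[i, ] <- zbar
  mw <- pathgcn:::margin_weights(fit)
  expect_equal(as.vector((ZA[i, ] - zbar) * mw$w), c(0, 0))
})

test_that("local accuracy holds exactly for every explained sample (linear head)", {
  toy <- shap_toy(seed = 9, n_pathways = 4, pool_channels = 3)
  sh <- shap_pooling(toy$fit, toy$fx$train)
  expect_equal(rowSums(sh$values) + sh$base, sh$margin, tolerance = 1e-8)
})

test_that("exact values equal brute-force coalition enumeration (<= 10 features)", {
  toy <- shap_toy(seed = 13, n_pathways = 5, pool_channels = 2)  # 10 features
  fit <- toy$fit
  Z <- pooled_activations(fit, toy$fx$train)
  sh <- shap_pooling(fit, toy$fx$train)
  mw <- pathgcn:::margin_weights(fit)
  zbar <- colMeans(Z)
  f <- function(z) sum(mw$w * z) + mw$b
  for (i in c(1, 4, 9)) {
    phi_brute <- brute_shapley(f, Z[i, ], zbar)
    expect_equal(sh$values[i, ], phi_brute, tolerance = 1e-8)
  }
})

test_that("duplicating a pooled feature with half its weight splits the attribution", {
  toy <- shap_toy(seed = 15, n_pathways = 2, pool_channels = 2)
  fit <- toy$fit
  Z <- pooled_activations(fit, toy$fx$train)
  w <- c(1.5, -0.4, 0.8, 0.2)
  zbar <- colMeans(Z)
  phi <- t((t(Z) - zbar) * w)
  # duplicate feature 1 with half weight: each copy carries half of phi_1
  Zdup <- cbind(Z, Z[, 1])
  wdup <- c(w[1] / 2, w[-1], w[1] / 2)
  phidup <- t((t(Zdup) - colMeans(Zdup)) * wdup)
  expect_equal(phidup[, 1] + phidup[, 5], phi[, 1], tolerance = 1e-12)
  expect_equal(phidup[, 1], phi[, 1] / 2, tolerance = 1e-12)
})

test_that("sampled estimator (nonlinear head) keeps approximate local accuracy", {
  fx <- tiny_fixture(seed = 19, n_pathways = 3, n_per_class = 6)
  cfg <- model_config(arch = "gcn_mlp", hidden_channels = 3, pool_channels = 2,
                      mlp_hidden = c(5, 3), seed = 8)
  m <- build_model(fx$graphs, fx$train$gene_ids, cfg)
  fit <- structure(list(model = m, config = cfg, cutoff = 0.5,
                        class_names = fx$train$class_names),
                   class = "trained_model")
  sh <- shap_pooling(fit, fx$train, n_perm = 48, seed = 4)
  err <- abs(rowSums(sh$values) + sh$base - sh$margin)
  expect_lt(mean(err), 0.05 * mean(abs(sh$margin)) + 0.02)
})

test_that("pathway aggregation averages |values| over channels and samples", {
  vals <- rbind(c(0.1, -0.3), c(0.2, 0.0))
  sh <- list(values = vals, feature_pathway = c("P1", "P1"))
  tab <- aggregate_pathway_importance(sh)
  expect_equal(tab$entries$mean_abs_shap, 0.15)   # (0.1+0.3+0.2+0)/4
  # ranking and stable order on ties / zeros
  vals2 <- matrix(c(0, 0, 0.2, 0.2, 0, 0), 2, 3)  # one channel per pathway
  sh2 <- list(values = vals2, feature_pathway = c("A", "B", "C"))
  tab2 <- aggregate_pathway_importance(sh2)
  expect_equal(tab2$entries$id, c("B", "A", "C"))
  expect_equal(tab2$entries$rank, 1:3)
  sh3 <- list(values = vals2 * 0, feature_pathway = c("A", "B", "C"))
  expect_equal(aggregate_pathway_importance(sh3)$entries$id, c("A", "B", "C"))
})

test_that("gene-level attributions: constant and dead inputs get zero importance", {
  toy <- shap_toy(seed = 23, n_pathways = 3)
  fx <- toy$fx
  fit <- toy$fit
  # make one gene behave as never-measured: constant zero for all samples
  fx$train$values[, 5] <- 0
  gt <- shap_genes(fit, fx$train, background_size = 4, n_steps = 8, seed = 2)
  expect_equal(dim(gt$per_sample_values), dim(fx$train$values))
  expect_true(all(gt$per_sample_values[, 5] == 0))
  expect_equal(gt$entries$mean_abs_shap[gt$entries$id == fx$train$gene_ids[5]], 0)
  # zero conv weights kill every gene attribution
  fit0 <- fit
  fit0$model$params$W0[] <- 0
  gt0 <- shap_genes(fit0, fx$train, background_size = 4, n_steps = 4, seed = 2)
  expect_true(all(abs(gt0$per_sample_values) < 1e-12))
  # local accuracy of the expected-gradients estimator
  expect_lt(gt$local_accuracy, 0.05)
})

test_that("compare_rankings: identical, reversed, and random-overlap expectation", {
  ids <- sprintf("P%02d", 1:20)
  mk_tab <- function(order_ids) {
    structure(list(level = "pathway",
                   entries = data.frame(id = order_ids,
                                        mean_abs_shap = seq(1, 0.05, length.out = 20),
                                        rank = 1:20)),
              class = "importance_table")
  }
  enr <- function(order_ids) {
    data.frame(pathway_id = order_ids, nes = seq(2, 0.1, length.out = 20))
  }
  expect_equal(compare_rankings(mk_tab(ids), enr(ids), 5)$n_overlap, 5)
  expect_equal(compare_rankings(mk_tab(ids), enr(rev(ids)), 5)$n_overlap, 0)
  expect_warning(res <- compare_rankings(mk_tab(ids), enr(ids), 50), "clipped")
  expect_equal(res$n_overlap, 20)
  # E[overlap] for independent rankings = top_n^2 / N = 25/20
  set.seed(91)
  ov <- replicate(4000, {
    a <- sample(ids); b <- sample(ids)
    length(intersect(a[1:5], b[1:5]))
  })
  expect_equal(mean(ov), 25 / 20, tolerance = 0.05)
})
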