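make_ds <- function(values, labels) {
  expression_dataset(values, labels, c("class0", "class1"))
}

test_that("rank_genes: signal-to-noise with the sd floor, antisymmetry", {
  set.seed(4)
  n <- 10
  vals <- cbind(flat = rep(c(5, 5), each = n / 2) + rep(c(0, 0), each = n / 2),
                up = c(rnorm(n / 2, 2, 0.5), rnorm(n / 2, 0, 0.5)),
                noise = rnorm(n))
  # make 'flat' truly identical across classes
  vals[, "flat"] <- 5
  vals <- vals + cbind(rnorm(n, sd = 1e-9), 0, 0)  # avoid constant-row issues
  rownames(vals) <- sprintf("s%d", 1:n)
  ds <- make_ds(vals, rep(c("class0", "class1"), each = n / 2))
  r <- rank_genes(ds)
  expect_equal(r$score[r$gene == "flat"], 0, tolerance = 1e-6)
  # hand case: means 2 and 0, sample sds 0.5 and 0.5 -> score 2
  a <- 0.5 * sqrt(3) / 2   # alternating +/- a around the mean gives sd 0.5
  v2 <- cbind(g = c(rep(2, 4), rep(0, 4)) + rep(c(a, -a), 4),
              pad = rnorm(8))
  rownames(v2) <- sprintf("t%d", 1:8)
  ds2 <- make_ds(v2, rep(c("class0", "class1"), each = 4))
  r2 <- rank_genes(ds2)
  sc <- r2$score[r2$gene == "g"]
  expect_equal(sc, 2, tolerance = 0.01)
  # negating all values flips signs and reverses order
  ds_neg <- make_ds(-v2, rep(c("class0", "class1"), each = 4))
  r_neg <- rank_genes(ds_neg)
  expect_equal(r_neg$gene, rev(r2$gene))
  expect_equal(r_neg$score[r_neg$gene == "g"], -sc, tolerance = 1e-9)
  expect_error(rank_genes(make_ds(v2, c("class0", rep("class1", 7)))),
               "at least 2")
})

test_that("enrichment_score reproduces hand-enumerated running sums", {
  ranked <- data.frame(gene = c("g1", "g2", "g3", "g4"), score = c(3, 2, 1, 0.5))
  # S = {g1}, p = 0: running (1, 2/3, 1/3, 0), ES = 1
  r <- enrichment_score(ranked, "g1", weight_p = 0)
  expect_equal(r$running, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(r$es, 1)
  # S = all genes: ES = 1
  expect_equal(enrichment_score(ranked, ranked$gene)$es, 1)
  # S = {g4} at the bottom, p = 0: ES negative (brute-force agreement)
  r4 <- enrichment_score(ranked, "g4", weight_p = 0)
  expect_lt(r4$es, 0)
  expect_equal(r4$es, brute_es(ranked$score, ranked$gene %in% "g4", 0))
  # empty intersection flagged
  r0 <- enrichment_score(ranked, "zz")
  expect_false(r0$computable)
  expect_true(is.na(r0$es))
})

test_that("enrichment_score matches the brute-force oracle on random instances", {
  set.seed(7)
  for (rep in 1:200) {
    N <- sample(5:30, 1)
    genes <- sprintf("g%02d", 1:N)
    scores <- sort(round(rnorm(N), 2), decreasing = TRUE)
    ranked <- data.frame(gene = genes, score = scores)
    set_size <- sample(1:(N - 1), 1)
    gs <- sample(genes, set_size)
    p <- sample(c(0, 1, 1.5), 1)
    r <- enrichment_score(ranked, gs, p)
    expect_equal(r$es, brute_es(scores, genes %in% gs, p), tolerance = 1e-12)
  }
})

test_that("single-gene set, p = 0: ES matches the rank-position closed form", {
  for (N in 2:10) {
    genes <- sprintf("g%d", 1:N)
    ranked <- data.frame(gene = genes, score = seq(N, 1))
    for (r_pos in 1:N) {
      es <- enrichment_score(ranked, genes[r_pos], weight_p = 0)$es
      hit_peak <- 1 - (r_pos - 1) / (N - 1)      # value right after the hit
      miss_trough <- -(r_pos - 1) / (N - 1)      # value just before the hit
      # on an exact tie the trough comes first in the running sum
      expected <- if (abs(hit_peak) > abs(miss_trough)) hit_peak else miss_trough
      expect_equal(es, expected, tolerance = 1e-12)
    }
  }
})

test_that("enrichment_score agrees with fgsea's statistic on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  for (rep in 1:25) {
    N <- sample(10:40, 1)
    genes <- sprintf("g%02d", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- genes
    gs <- sample(genes, sample(2:(N - 2), 1))
    ours <- enrichment_score(data.frame(gene = genes, score = scores), gs,
                             weight_p = 1)$es
    theirs <- fgsea::calcGseaStat(scores, selectedStats = which(genes %in% gs),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("permutation statistics: planted set detected, conventions honored", {
  set.seed(21)
  n <- 40
  G <- 60
  vals <- matrix(rnorm(n * G), n, G,
                 dimnames = list(sprintf("s%d", 1:n), sprintf("g%02d", 1:G)))
  vals[1:(n / 2), 1:8] <- vals[1:(n / 2), 1:8] + 1.5   # class0-up set
  ds <- make_ds(vals, rep(c("class0", "class1"), each = n / 2))
  sets <- gene_set_collection(list(planted = sprintf("g%02d", 1:8),
                                   null1 = sprintf("g%02d", 21:30),
                                   null2 = sprintf("g%02d", 31:40)))
  res <- permutation_stats(ds, sets, n_perm = 200, seed = 5)
  pl <- res[res$pathway_id == "planted", ]
  expect_gt(pl$es, 0)
  expect_equal(sign(pl$nes), sign(pl$es))
  expect_lte(pl$p_value, 0.01)
  expect_lt(pl$fdr_q, 0.25)
  expect_equal(pl$direction, "class0-enriched")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  # determinism
  res2 <- permutation_stats(ds, sets, n_perm = 200, seed = 5)
  expect_identical(res, res2)
  expect_error(permutation_stats(ds, sets, n_perm = 5), "at least 10")
})
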