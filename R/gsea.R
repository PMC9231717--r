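# Gene set enrichment analysis (weighted KS, phenotype permutation) ----------
#
# Classic two-phenotype enrichment: genes are ranked by a signal-to-noise
# ratio between the two classes, each set is scored by the weighted
# Kolmogorov-Smirnov running-sum statistic (weight exponent p = 1 by
# default), and significance comes from phenotype-label permutation:
# per-set null ES distributions give sign-matched normalized enrichment
# scores (NES), permutation p-values, and FDR q-values from the ratio of
# null to observed NES tail fractions. Positive scores/ES mean enrichment in
# the first class (class0), negative in the second, matching the ranking
# metric (mean0 - mean1)/(sd0 + sd1).

#' Signal-to-noise gene ranking
#'
#' Per gene: `(mean0 - mean1) / (sd0 + sd1)` with sample standard deviations
#' floored at `0.2 * |mean|` per class (and at 0.2 when the class mean is 0),
#' the usual guard against near-constant genes. Output is sorted descending;
#' ties keep the input gene order (stable).
#'
#' @param ds An `expression_dataset`.
#' @return data.frame `gene`, `score`, sorted by decreasing score.
#' @export
rank_genes <- function(ds) {
  labs <- ds$labels
  if (any(table(labs) < 2)) stop("each class needs at least 2 samples")
  i0 <- labs == levels(labs)[1]
  x0 <- ds$values[i0, , drop = FALSE]
  x1 <- ds$values[!i0, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  s0 <- apply(x0, 2, sd); s1 <- apply(x1, 2, sd)
  floor_sd <- function(s, m) {
    lo <- ifelse(abs(m) > 0, 0.2 * abs(m), 0.2)
    pmax(s, lo)
  }
  n_floored <- sum(s0 < floor_sd(s0, m0) * (1 - 1e-12)) +
    sum(s1 < floor_sd(s1, m1) * (1 - 1e-12))
  score <- (m0 - m1) / (floor_sd(s0, m0) + floor_sd(s1, m1))
  ord <- order(-score)   # stable for ties
  out <- data.frame(gene = ds$gene_ids[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "n_sd_floored") <- n_floored
  out
}

#' Weighted KS enrichment score
#'
#' Walks the ranked list; at a set member ("hit") the running sum rises by
#' `|score|^p / sum(|score of hits|^p)`, at a non-member it falls by
#' `1/(N - |S|)`. The enrichment score is the running-sum value of maximal
#' absolute deviation from zero (sign kept).
#'
#' @param ranked data.frame from [rank_genes()] (columns `gene`, `score`).
#' @param gene_set Character vector of member genes.
#' @param weight_p Weight exponent (1 = classic weighted statistic,
#'   0 = unweighted KS).
#' @return List: `es`, `running` (length-N running sum), `hits` (logical),
#'   `computable` (FALSE when the set does not intersect the list, in which
#'   case `es` is `NA`).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  hits <- genes %in% gene_set
  N <- length(genes)
  nh <- sum(hits)
  if (nh == 0) {
    return(list(es = NA_real_, running = rep(NA_real_, N), hits = hits,
                computable = FALSE))
  }
  w <- abs(ranked$score)^weight_p
  w[!hits] <- 0
  denom_hit <- sum(w)
  inc <- numeric(N)
  if (denom_hit > 0) {
    inc[hits] <- w[hits] / denom_hit
  } else {
    inc[hits] <- 1 / nh        # all hit weights zero: fall back to equal steps
  }
  if (N > nh) inc[!hits] <- -1 / (N - nh)
  running <- cumsum(inc)
  # earliest extreme wins ties (within numerical tolerance of the max |.|)
  idx <- which(abs(running) >= max(abs(running)) - 1e-12)[1]
  es <- running[idx]
  list(es = es, running = running, hits = hits, computable = TRUE)
}

#' Phenotype-permutation enrichment statistics
#'
#' Ranks genes, scores every set, then permutes the phenotype labels
#' `n_perm` times (redrawing any permutation that leaves a class with fewer
#' than two samples) to build per-set null ES distributions. NES is
#' ES divided by the mean |null ES| of matching sign; the p-value is the
#' fraction of same-sign null ES at least as extreme; the FDR q-value is the
#' standard ratio of null-to-observed NES tail fractions, clipped to [0, 1].
#'
#' @param ds An `expression_dataset`.
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of label permutations (>= 10).
#' @param seed Integer seed.
#' @param weight_p Weight exponent passed to [enrichment_score()].
#' @return data.frame: `pathway_id`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `direction`, `size`.
#' @export
permutation_stats <- function(ds, sets, n_perm = 1000, seed = 1,
                              weight_p = 1) {
  if (n_perm < 10) stop("n_perm must be at least 10")
  set.seed(seed)
  ids <- names(sets$sets)
  K <- length(ids)
  score_all <- function(d) {
    ranked <- rank_genes(d)
    vapply(ids, function(k) {
      enrichment_score(ranked, sets$sets[[k]], weight_p)$es
    }, numeric(1))
  }
  es_obs <- score_all(ds)
  labs <- as.character(ds$labels)
  null_es <- matrix(NA_real_, n_perm, K)
  for (r in seq_len(n_perm)) {
    repeat {
      perm <- sample(labs)
      if (min(table(factor(perm, levels = ds$class_names))) >= 2) break
    }
    dperm <- expression_dataset(ds$values, perm, ds$class_names)
    null_es[r, ] <- score_all(dperm)
  }

  nes <- numeric(K); pval <- numeric(K)
  null_nes <- matrix(NA_real_, n_perm, K)
  for (k in seq_len(K)) {
    nk <- null_es[, k]
    mpos <- mean(nk[nk >= 0]); mneg <- mean(abs(nk[nk < 0]))
    norm_one <- function(e) {
      if (is.na(e) || e == 0) return(0)
      if (e > 0) {
        if (is.nan(mpos) || mpos == 0) 0 else e / mpos
      } else {
        if (is.nan(mneg) || mneg == 0) 0 else e / mneg
      }
    }
    nes[k] <- norm_one(es_obs[k])
    null_nes[, k] <- vapply(nk, norm_one, numeric(1))
    e <- es_obs[k]
    if (is.na(e)) {
      pval[k] <- NA_real_
    } else if (e == 0) {
      pval[k] <- 1
    } else if (e > 0) {
      same <- nk[nk >= 0]
      pval[k] <- if (length(same) == 0) 0 else mean(same >= e)
    } else {
      same <- nk[nk < 0]
      pval[k] <- if (length(same) == 0) 0 else mean(same <= e)
    }
  }

  all_null_nes <- as.vector(null_nes)
  fdr <- vapply(seq_len(K), function(k) {
    nstar <- nes[k]
    if (is.na(nstar) || nstar == 0) return(1)
    if (nstar > 0) {
      null_tail <- mean(all_null_nes[all_null_nes >= 0] >= nstar)
      obs_tail <- mean(nes[nes >= 0] >= nstar)
    } else {
      null_tail <- mean(all_null_nes[all_null_nes < 0] <= nstar)
      obs_tail <- mean(nes[nes < 0] <= nstar)
    }
    if (is.nan(null_tail)) null_tail <- 0
    if (is.nan(obs_tail) || obs_tail == 0) return(1)
    min(1, max(0, null_tail / obs_tail))
  }, numeric(1))

  data.frame(pathway_id = ids,
             es = unname(es_obs),
             nes = nes,
             p_value = pval,
             fdr_q = fdr,
             direction = ifelse(es_obs >= 0,
                                paste0(ds$class_names[1], "-enriched"),
                                paste0(ds$class_names[2], "-enriched")),
             size = lengths(sets$sets)[ids],
             stringsAsFactors = FALSE, row.names = NULL)
}
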