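# Shared fixtures and independent brute-force oracles used across tests.

# tiny prepared fixture (graphs + aligned train/test) for model-level tests
tiny_fixture <- function(seed = 42, n_pathways = 6, n_per_class = 15,
                         n_informative = min(2, n_pathways),
                         genes_per_pathway = c(4, 8)) {
  spec <- fixture_spec(n_pathways = n_pathways,
                       genes_per_pathway = genes_per_pathway,
                       n_samples_per_class = n_per_class,
                       n_informative_pathways = n_informative,
                       seed = seed)
  make_fixture(spec)
}

# brute-force D^{-1/2} (A + I) D^{-1/2} from a dense adjacency
brute_norm_adjacency <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  Dh <- diag(1 / sqrt(d), nrow(A))
  Dh %*% At %*% Dh
}

# random undirected binary graph on n nodes (dense adjacency)
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  if (n > 1) {
    up <- which(upper.tri(A))
    on <- up[runif(length(up)) < p]
    A[on] <- 1
    A <- A + t(A)
  }
  A
}

# exact Shapley values of f over n features by coalition enumeration
brute_shapley <- function(f, x, background) {
  n <- length(x)
  phi <- numeric(n)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v <- function(mask) {
    z <- background
    z[mask] <- x[mask]
    f(z)
  }
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(subsets))) {
      mask <- as.logical(subsets[r, ])
      if (mask[i]) next
      s <- sum(mask)
      wgt <- factorial(s) * factorial(n - s - 1) / factorial(n)
      with_i <- mask
      with_i[i] <- TRUE
      phi[i] <- phi[i] + wgt * (v(with_i) - v(mask))
    }
  }
  phi
}

# brute-force weighted-KS enrichment score: explicit running-sum vector
brute_es <- function(scores, hits, p = 1) {
  N <- length(scores)
  nh <- sum(hits)
  w <- abs(scores)^p
  denom <- sum(w[hits])
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      cur <- cur + if (denom > 0) w[i] / denom else 1 / nh
    } else {
      cur <- cur - 1 / (N - nh)
    }
    running[i] <- cur
  }
  # same tie rule as the implementation: earliest extreme within tolerance
  running[which(abs(running) >= max(abs(running)) - 1e-12)[1]]
}

# textbook confusion-matrix metrics (independent of compute_metrics)
brute_metrics <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       precision = prec, recall = rec, f1 = f1)
}

# brute-force Youden scan over all observed thresholds (score >= t -> positive)
brute_youden <- function(scores, pos) {
  cand <- c(sort(unique(scores)), Inf)
  j <- sapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & pos) / sum(pos) + sum(!pred & !pos) / sum(!pos) - 1
  })
  max(j)
}
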