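# Synthetic fixtures: pathways, edges, two-class expression ------------------
#
# Emulates the structure of a curated-pathway microarray study: a few dozen
# to a few hundred overlapping gene sets with sparse within-set edges
# (Erdos-Renyi at a target density around 0.15), and two balanced sample
# classes. Planted signal comes in two flavours:
#   * mean_shift: member genes of an informative pathway differ in mean
#     between classes by delta (detectable by per-gene statistics and GSEA);
#   * correlation_flip: member genes load on a shared latent factor whose
#     loading signs depend on the class, so every gene's marginal
#     distribution is identical across classes while the within-pathway
#     correlation structure flips (invisible to per-gene statistics and
#     GSEA's ranking, visible to a nonlinear graph model).
# The generator writes the same file formats the real-data interfaces read,
# plus a manifest recording the planted truth.

#' Fixture specification
#'
#' @param n_pathways Number of pathways.
#' @param genes_per_pathway Length-2 integer range of pathway sizes.
#' @param overlap_fraction Fraction of each pathway's genes shared with its
#'   predecessor pathway.
#' @param edge_density Erdos-Renyi edge probability within a pathway.
#' @param n_samples_per_class Samples per class (per split).
#' @param n_informative_pathways Planted pathways (split as evenly as
#'   possible between the two effect types, mean-shift first).
#' @param mean_shift Between-class mean difference delta on mean-shift
#'   pathway genes.
#' @param correlation_r Latent-factor correlation magnitude for
#'   correlation-flip pathways (in (0, 1)).
#' @param noise_sd Baseline i.i.d. Gaussian noise SD.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_pathways = 40, genes_per_pathway = c(20, 40),
                         overlap_fraction = 0.1, edge_density = 0.15,
                         n_samples_per_class = 100,
                         n_informative_pathways = 4, mean_shift = 1,
                         correlation_r = 0.8, noise_sd = 1, seed = 1) {
  stopifnot(n_informative_pathways <= n_pathways,
            edge_density > 0, edge_density <= 1,
            overlap_fraction >= 0, overlap_fraction < 1,
            correlation_r > 0, correlation_r < 1,
            length(genes_per_pathway) == 2,
            genes_per_pathway[1] >= 2)
  structure(list(n_pathways = n_pathways,
                 genes_per_pathway = as.integer(genes_per_pathway),
                 overlap_fraction = overlap_fraction,
                 edge_density = edge_density,
                 n_samples_per_class = as.integer(n_samples_per_class),
                 n_informative_pathways = as.integer(n_informative_pathways),
                 mean_shift = mean_shift, correlation_r = correlation_r,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate pathways and their edge lists
#'
#' Pathway sizes are drawn uniformly from the configured range; an
#' `overlap_fraction` of each pathway's genes is borrowed from the previous
#' pathway; edges are Erdos-Renyi at the target density. Reproducible from
#' the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return List: `sets` (a [gene_set_collection()]), `edges` (named list as
#'   from [read_edge_list()]), `edge_df` (flat data.frame).
#' @export
make_pathways <- function(spec) {
  set.seed(spec$seed)
  K <- spec$n_pathways
  sizes <- sample(spec$genes_per_pathway[1]:spec$genes_per_pathway[2], K,
                  replace = TRUE)
  sets <- vector("list", K)
  gene_counter <- 0L
  for (k in seq_len(K)) {
    n_shared <- if (k > 1) min(floor(spec$overlap_fraction * sizes[k]),
                               length(sets[[k - 1]])) else 0L
    shared <- if (n_shared > 0) sets[[k - 1]][seq_len(n_shared)] else character(0)
    n_new <- sizes[k] - n_shared
    if (n_new < 0) stop("infeasible overlap for pathway ", k)
    new_genes <- sprintf("G%05d", gene_counter + seq_len(n_new))
    gene_counter <- gene_counter + n_new
    sets[[k]] <- c(shared, new_genes)
  }
  names(sets) <- sprintf("PW%03d", seq_len(K))
  coll <- gene_set_collection(sets, source_name = "synthetic")
  edge_rows <- lapply(names(sets), function(k) {
    g <- sets[[k]]
    pairs <- utils::combn(g, 2)
    keep <- runif(ncol(pairs)) < spec$edge_density
    if (!any(keep)) return(NULL)
    data.frame(pathway = k, gene_a = pairs[1, keep], gene_b = pairs[2, keep],
               stringsAsFactors = FALSE)
  })
  edge_df <- do.call(rbind, Filter(Negate(is.null), edge_rows))
  edges <- setNames(vector("list", K), names(sets))
  for (k in names(sets)) {
    rows <- edge_df[edge_df$pathway == k, , drop = FALSE]
    edges[[k]] <- as.matrix(rows[, c("gene_a", "gene_b")])
    dimnames(edges[[k]]) <- NULL
  }
  list(sets = coll, edges = edges, edge_df = edge_df)
}

# planted-truth bookkeeping: which pathways carry which effect
planted_truth <- function(spec, sets) {
  ids <- names(sets$sets)
  ni <- spec$n_informative_pathways
  informative <- ids[seq_len(ni)]
  n_shift <- ceiling(ni / 2)
  list(informative = informative,
       mean_shift = informative[seq_len(n_shift)],
       correlation_flip = if (ni > n_shift)
         informative[(n_shift + 1):ni] else character(0))
}

# one split of expression data (raw intensity-like scale, genes x samples)
draw_split <- function(spec, sets, truth, n_per_class, prefix) {
  universe <- gene_universe(sets)
  G <- length(universe)
  n <- 2 * n_per_class
  labels <- rep(c("class0", "class1"), each = n_per_class)
  X <- matrix(rnorm(n * G, sd = spec$noise_sd), n, G,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n)), universe))
  for (k in truth$mean_shift) {
    g <- sets$sets[[k]]
    X[labels == "class1", g] <- X[labels == "class1", g] + spec$mean_shift
  }
  r <- spec$correlation_r
  for (k in truth$correlation_flip) {
    g <- sets$sets[[k]]
    m <- length(g)
    fac <- rnorm(n)
    signs0 <- rep(1, m)
    signs1 <- rep(c(1, -1), length.out = m)
    load <- outer(fac, rep(sqrt(r), m))
    eps <- matrix(rnorm(n * m), n, m)
    base <- load * rep(1, n) %o% signs0
    base[labels == "class1", ] <- (load * rep(1, n) %o% signs1)[labels == "class1", ]
    X[, g] <- spec$noise_sd * (base + sqrt(1 - r) * eps)
  }
  list(values = X, labels = setNames(labels, rownames(X)))
}

#' Generate train and test expression datasets
#'
#' Draws two independent splits under the same planted truth. The returned
#' matrices are on the "intensity-like" raw scale (standardize and align via
#' [preprocess_expression()] or use [standardize_per_sample()] +
#' [align_to_universe()] directly; the generator's values may be negative,
#' so the log2 step is normally skipped for synthetic data).
#'
#' @param spec A [fixture_spec()].
#' @param sets Output of [make_pathways()] (`$sets`), so pathway membership
#'   is consistent.
#' @return List: `train`, `test` (each `values` samples x genes + `labels`),
#'   `truth` (planted pathway ids by effect type).
#' @export
make_expression <- function(spec, sets) {
  truth <- planted_truth(spec, sets)
  set.seed(spec$seed + 1L)
  train <- draw_split(spec, sets, truth, spec$n_samples_per_class, "TR")
  set.seed(spec$seed + 2L)
  test <- draw_split(spec, sets, truth, spec$n_samples_per_class, "TE")
  list(train = train, test = test, truth = truth)
}

#' Prepared (standardized, aligned) datasets from a fixture spec
#'
#' Convenience wrapper: generates pathways, edges and both splits, applies
#' per-sample standardization and universe alignment, and builds the graphs.
#'
#' @param spec A [fixture_spec()].
#' @return List: `sets`, `graphs`, `train`, `test` (aligned
#'   `expression_dataset`s), `truth`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  pw <- make_pathways(spec)
  expr <- make_expression(spec, pw$sets)
  prep <- function(split) {
    ds <- expression_dataset(standardize_per_sample(split$values),
                             split$labels, c("class0", "class1"))
    suppressMessages(align_to_universe(ds, pw$sets))
  }
  graphs <- build_pathway_graphs(pw$sets, pw$edges)
  list(sets = pw$sets, graphs = graphs,
       train = prep(expr$train), test = prep(expr$test),
       truth = expr$truth)
}

#' Write a complete fixture to disk
#'
#' Emits `sets.gmt`, `edges.tsv`, `train_expression.tsv`,
#' `train_labels.tsv`, `test_expression.tsv`, `test_labels.tsv` and
#' `manifest.json` (the planted truth and the spec) into `dir`. Expression
#' files are genes x samples, matching [read_expression_tsv()].
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
end_to_end_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pw <- make_pathways(spec)
  expr <- make_expression(spec, pw$sets)
  write_gmt(pw$sets, file.path(dir, "sets.gmt"))
  write.table(pw$edge_df, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (split in c("train", "test")) {
    s <- expr[[split]]
    write_expression_tsv(t(s$values), file.path(dir, paste0(split, "_expression.tsv")))
    write.table(data.frame(sample_id = names(s$labels), label = s$labels),
                file.path(dir, paste0(split, "_labels.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest <- list(spec = unclass(spec),
                   informative = expr$truth$informative,
                   mean_shift = expr$truth$mean_shift,
                   correlation_flip = expr$truth$correlation_flip)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
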