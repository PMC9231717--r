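# Per-pathway gene graphs and their normalized adjacency operators -----------
#
# Each pathway is an undirected, unweighted graph over its member genes.
# Graph convolution uses the symmetric normalization
#   S = D~^{-1/2} (A + I) D~^{-1/2},  D~_ii = sum_j (A + I)_ij,
# i.e. self-loops are added before degree normalization, so S is symmetric,
# nonnegative, with strictly positive diagonal. Node identity is
# (pathway_id, gene): a gene in several pathways is a distinct node in each.

#' Read a pathway edge list
#'
#' Tab-separated file with header `pathway`, `gene_a`, `gene_b`, one
#' within-pathway gene pair per row. Edges are restricted to pairs whose
#' endpoints both belong to the named set; `(a,b)`/`(b,a)` duplicates collapse
#' to one undirected edge; self-pairs are dropped. Rows naming an unknown
#' pathway or a gene outside its set are dropped with a single summary
#' warning.
#'
#' @param path Path to the edge-list TSV.
#' @param sets A [gene_set_collection()] giving each pathway's membership.
#' @return Named list (one element per pathway in `sets`, including pathways
#'   with no edges) of two-column character matrices of undirected edges.
#' @export
read_edge_list <- function(path, sets) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", quote = "")
  if (ncol(df) < 3L) stop("edge list needs columns pathway, gene_a, gene_b")
  names(df)[1:3] <- c("pathway", "gene_a", "gene_b")

  out <- setNames(vector("list", n_sets(sets)), names(sets$sets))
  for (k in names(out)) out[[k]] <- matrix(character(), ncol = 2)
  n_unknown <- 0L; n_foreign <- 0L; n_self <- 0L

  if (nrow(df) > 0) {
    known <- df$pathway %in% names(sets$sets)
    n_unknown <- sum(!known)
    df <- df[known, , drop = FALSE]
    keep_self <- df$gene_a != df$gene_b
    n_self <- sum(!keep_self)
    df <- df[keep_self, , drop = FALSE]
    if (nrow(df) > 0) {
      in_set <- vapply(seq_len(nrow(df)), function(i) {
        s <- sets$sets[[df$pathway[i]]]
        (df$gene_a[i] %in% s) && (df$gene_b[i] %in% s)
      }, logical(1))
      n_foreign <- sum(!in_set)
      df <- df[in_set, , drop = FALSE]
    }
    if (nrow(df) > 0) {
      a <- pmin(df$gene_a, df$gene_b)
      b <- pmax(df$gene_a, df$gene_b)
      key <- paste(df$pathway, a, b, sep = "\r")
      keep <- !duplicated(key)
      df <- data.frame(pathway = df$pathway[keep], gene_a = a[keep],
                       gene_b = b[keep], stringsAsFactors = FALSE)
      for (k in unique(df$pathway)) {
        rows <- df$pathway == k
        out[[k]] <- cbind(df$gene_a[rows], df$gene_b[rows])
      }
    }
  }
  dropped <- n_unknown + n_foreign + n_self
  if (dropped > 0) {
    warning(sprintf(paste0("dropped %d edge rows (%d unknown pathway, ",
                           "%d gene outside its set, %d self-pairs)"),
                    dropped, n_unknown, n_foreign, n_self))
  }
  out
}

#' Build one pathway graph
#'
#' Constructs the binary symmetric adjacency `A` (zero diagonal) over `genes`
#' in the given order and its normalized operator
#' `S = D~^{-1/2}(A + I)D~^{-1/2}` with `D~` the degree matrix of `A + I`.
#' Genes not touched by any edge stay as isolated nodes (their only nonzero
#' entry in `S` is the self-loop, value 1).
#'
#' @param pathway_id Pathway identifier.
#' @param genes Character vector of member genes (node order).
#' @param edges Two-column character matrix of undirected gene pairs; every
#'   endpoint must appear in `genes`.
#' @return An object of class `pathway_graph` with fields `pathway_id`,
#'   `nodes`, `adjacency` (dgCMatrix), `norm_adjacency` (dgCMatrix).
#' @export
build_graph <- function(pathway_id, genes, edges = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in pathway ", pathway_id)
  n <- length(genes)
  if (n == 0) stop("pathway ", pathway_id, " has no genes")
  if (is.null(edges) || NROW(edges) == 0) {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  } else {
    ia <- match(edges[, 1], genes)
    ib <- match(edges[, 2], genes)
    if (anyNA(ia) || anyNA(ib)) {
      stop("edge endpoint not in gene list for pathway ", pathway_id)
    }
    keep <- ia != ib
    ia <- ia[keep]; ib <- ib[keep]
    A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                              x = 1, dims = c(n, n), use.last.ij = TRUE)
  }
  A <- methods::as(A, "CsparseMatrix")
  Atil <- A + Matrix::Diagonal(n)
  dtil <- Matrix::rowSums(Atil)
  Dhalf <- Matrix::Diagonal(n, x = 1 / sqrt(dtil))
  S <- Dhalf %*% Atil %*% Dhalf
  structure(list(pathway_id = pathway_id,
                 nodes = genes,
                 adjacency = methods::as(A, "generalMatrix"),
                 norm_adjacency = methods::as(S, "generalMatrix")),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf("pathway_graph '%s': %d nodes, %d edges (density %.3f)\n",
              x$pathway_id, s$n_nodes, s$n_edges, s$edge_density))
  invisible(x)
}

#' Build all pathway graphs from a collection and an edge list
#'
#' @param sets A [gene_set_collection()].
#' @param edges Result of [read_edge_list()], or `NULL` for edgeless graphs.
#' @return Named list of `pathway_graph` objects, in set order.
#' @export
build_pathway_graphs <- function(sets, edges = NULL) {
  ids <- names(sets$sets)
  out <- lapply(ids, function(k) {
    build_graph(k, sets$sets[[k]],
                if (is.null(edges)) NULL else edges[[k]])
  })
  setNames(out, ids)
}

#' Node/edge counts and edge density of a pathway graph
#'
#' Edge density is realized edges over possible unordered node pairs,
#' `n_edges / (n*(n-1)/2)`; it is defined as 0 for graphs with fewer than two
#' nodes.
#'
#' @param g A `pathway_graph`.
#' @return A one-row data.frame with `pathway_id`, `n_nodes`, `n_edges`,
#'   `edge_density`.
#' @export
graph_stats <- function(g) {
  n <- length(g$nodes)
  e <- as.integer(sum(g$adjacency != 0) / 2)
  dens <- if (n < 2) 0 else e / (n * (n - 1) / 2)
  data.frame(pathway_id = g$pathway_id, n_nodes = n, n_edges = e,
             edge_density = dens, stringsAsFactors = FALSE)
}

#' Stats table for a list of graphs
#' @param graphs Named list of `pathway_graph` objects.
#' @return data.frame, one row per graph.
#' @export
graph_stats_table <- function(graphs) {
  do.call(rbind, lapply(graphs, graph_stats))
}

#' Serialize graphs back to an edge-list data.frame
#'
#' Inverse of [read_edge_list()] + [build_pathway_graphs()]: emits one row per
#' undirected edge with endpoints in lexicographic order, pathways in
#' collection order. Used for round-trip checks and CLI export.
#'
#' @param graphs Named list of `pathway_graph` objects.
#' @return data.frame with columns `pathway`, `gene_a`, `gene_b`.
#' @export
graphs_to_edge_list <- function(graphs) {
  rows <- lapply(graphs, function(g) {
    A <- methods::as(g$adjacency, "TsparseMatrix")
    keep <- A@i < A@j
    if (!any(keep)) {
      return(data.frame(pathway = character(), gene_a = character(),
                        gene_b = character(), stringsAsFactors = FALSE))
    }
    a <- g$nodes[A@i[keep] + 1L]
    b <- g$nodes[A@j[keep] + 1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    ord <- order(lo, hi)
    data.frame(pathway = g$pathway_id, gene_a = lo[ord], gene_b = hi[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
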