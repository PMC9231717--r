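# Gene-set collections (GMT dialect) -----------------------------------------

#' Construct a gene-set collection
#'
#' A `gene_set_collection` is an ordered, named list of character vectors of
#' gene symbols (one vector per pathway) plus a source name. Pathway ids must
#' be unique and every set non-empty; a gene may belong to several sets, which
#' is the normal situation for curated pathway databases.
#'
#' @param sets Named list of character vectors of gene symbols, in pathway
#'   order. Genes are deduplicated within each set, keeping first occurrence.
#' @param source_name Free-text origin label (e.g. the GMT file name).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source_name = "unnamed") {
  if (length(sets) == 0) {
    out <- structure(list(sets = setNames(list(), character()),
                          source_name = source_name),
                     class = "gene_set_collection")
    return(out)
  }
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every gene set must have a non-empty pathway id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ",
         paste(ids[lengths(sets) == 0L], collapse = ", "))
  }
  structure(list(sets = sets, source_name = source_name),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, %d unique genes\n",
              x$source_name, length(x$sets),
              length(unique(unlist(x$sets, use.names = FALSE)))))
  invisible(x)
}

#' Number of sets in a collection
#' @param x A `gene_set_collection`.
#' @export
n_sets <- function(x) length(x$sets)

#' Union of member genes in first-appearance order
#'
#' The gene universe is the union of all set members, ordered by first
#' appearance across sets (set order, then within-set order). This order
#' defines the model's aligned input layout.
#'
#' @param x A `gene_set_collection`.
#' @return Character vector of gene symbols.
#' @export
gene_universe <- function(x) {
  unique(unlist(x$sets, use.names = FALSE))
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name`, `description`, then one or more gene symbols. Genes are
#' deduplicated within a set (first occurrence kept); duplicate set names are
#' an error; an empty file yields an empty collection with a warning.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("GMT file is empty: ", path)
    return(gene_set_collection(list(), source_name = basename(path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- ids
  gene_set_collection(sets, source_name = basename(path))
}

#' Write a collection to GMT
#'
#' @param x A `gene_set_collection`.
#' @param path Output file path.
#' @param descriptions Optional named character vector of per-set descriptions
#'   (defaults to `"na"` as in MSigDB exports).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  ids <- names(x$sets)
  desc <- if (is.null(descriptions)) rep("na", length(ids)) else descriptions[ids]
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], desc[i], x$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
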