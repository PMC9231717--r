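# Expression preprocessing ----------------------------------------------------
#
# Fixed pipeline: collapse probes -> log2 with cutoff -> per-sample
# standardization -> alignment to the pathway gene universe. Standardization
# precedes alignment, so zero-filled (never measured) genes stay exactly 0.

#' Construct an expression dataset
#'
#' Samples-by-genes matrix of continuous intensities with a two-class label
#' per sample.
#'
#' @param values Numeric matrix, samples in rows, genes in columns; dimnames
#'   used as sample and gene ids (required).
#' @param labels Character/factor vector, one of two class labels per sample.
#' @param class_names Length-2 character: `c(class0, class1)`. Defaults to the
#'   sorted unique labels. `class1` is the positive class throughout.
#' @return An object of class `expression_dataset` with fields `values`
#'   (samples x genes), `sample_ids`, `gene_ids`, `labels` (factor with levels
#'   `class_names`), `class_names`.
#' @export
expression_dataset <- function(values, labels, class_names = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have sample rownames and gene colnames")
  }
  if (length(labels) != nrow(values)) {
    stop("labels length must equal the number of samples")
  }
  labels <- as.character(labels)
  if (is.null(class_names)) class_names <- sort(unique(labels))
  if (length(class_names) != 2) stop("exactly two class names required")
  if (!all(labels %in% class_names)) {
    stop("labels outside class_names: ",
         paste(setdiff(unique(labels), class_names), collapse = ", "))
  }
  if (anyNA(values)) stop("expression values contain NA")
  structure(list(values = values,
                 sample_ids = rownames(values),
                 gene_ids = colnames(values),
                 labels = factor(labels, levels = class_names),
                 class_names = class_names),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("expression_dataset: %d samples x %d genes (%s=%d, %s=%d)\n",
              nrow(x$values), ncol(x$values),
              x$class_names[1], tab[[1]], x$class_names[2], tab[[2]]))
  invisible(x)
}

#' Collapse probe-level intensities to gene level
#'
#' Probes mapping to the same gene symbol are collapsed by the arithmetic
#' mean (a `"max"` rule is available); unmapped probes are dropped.
#'
#' @param probe_values Numeric matrix, probes x samples, probe ids as
#'   rownames.
#' @param probe_to_gene Named character vector: probe id -> gene symbol.
#'   Probes absent from the map (or mapping to `NA`/`""`) are unmapped.
#' @param method `"mean"` (default) or `"max"`.
#' @return Numeric matrix, genes x samples; gene order is first appearance in
#'   probe order.
#' @export
collapse_probes <- function(probe_values, probe_to_gene, method = c("mean", "max")) {
  method <- match.arg(method)
  probe_values <- as.matrix(probe_values)
  if (is.null(rownames(probe_values))) stop("probe_values needs probe rownames")
  genes <- probe_to_gene[rownames(probe_values)]
  mapped <- !is.na(genes) & nzchar(genes)
  if (!any(mapped)) stop("no probe maps to a gene symbol")
  pv <- probe_values[mapped, , drop = FALSE]
  genes <- genes[mapped]
  gene_order <- unique(genes)
  f <- factor(genes, levels = gene_order)
  fun <- if (method == "mean") colMeans else function(m) apply(m, 2, max)
  out <- t(vapply(split(seq_along(f), f), function(idx) {
    fun(pv[idx, , drop = FALSE])
  }, numeric(ncol(pv))))
  # vapply over a single sample collapses dims; restore
  if (ncol(pv) == 1) out <- matrix(out, ncol = 1, dimnames = list(gene_order, colnames(pv)))
  rownames(out) <- gene_order
  colnames(out) <- colnames(pv)
  out
}

#' Log2-transform with a lower cutoff
#'
#' Replaces every value `v` by `log2(max(v, cutoff))`; with the default
#' cutoff of 1 the output is nonnegative and low intensities are floored at 0.
#'
#' @param values Numeric matrix or vector.
#' @param cutoff Positive floor applied before the log (default 1).
#' @return Object of the same shape.
#' @export
log2_with_cutoff <- function(values, cutoff = 1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  log2(pmax(values, cutoff))
}

#' Standardize each sample to mean 0, variance 1
#'
#' Per-sample (row-wise) centering and scaling across genes, using the
#' population (1/N) variance. A constant row cannot be standardized and is an
#' error.
#'
#' @param values Numeric matrix, samples x genes.
#' @return Matrix of the same shape; each row has mean 0 and population
#'   variance 1.
#' @export
standardize_per_sample <- function(values) {
  values <- as.matrix(values)
  mu <- rowMeans(values)
  centered <- values - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  if (any(sd_pop == 0)) {
    bad <- which(sd_pop == 0)
    lab <- if (!is.null(rownames(values))) rownames(values)[bad] else bad
    stop("constant expression row(s), cannot standardize: ",
         paste(lab, collapse = ", "))
  }
  centered / sd_pop
}

#' Align a dataset to the pathway gene universe
#'
#' Reorders genes to the universe order ([gene_universe()]): genes listed in
#' a pathway but absent from the measured data are injected as exact-zero
#' columns; measured genes outside every pathway are dropped. Apply after
#' standardization so injected zeros survive.
#'
#' @param ds An `expression_dataset` (already standardized).
#' @param sets A [gene_set_collection()].
#' @return An `expression_dataset` over the universe genes, with attributes
#'   `n_injected` and `n_dropped` recording alignment bookkeeping.
#' @export
align_to_universe <- function(ds, sets) {
  universe <- gene_universe(sets)
  measured <- ds$gene_ids
  inject <- setdiff(universe, measured)
  dropped <- setdiff(measured, universe)
  vals <- matrix(0, nrow = nrow(ds$values), ncol = length(universe),
                 dimnames = list(ds$sample_ids, universe))
  common <- intersect(universe, measured)
  vals[, common] <- ds$values[, common, drop = FALSE]
  out <- expression_dataset(vals, as.character(ds$labels), ds$class_names)
  attr(out, "n_injected") <- length(inject)
  attr(out, "n_dropped") <- length(dropped)
  message(sprintf("aligned to universe of %d genes: %d zero-filled, %d dropped",
                  length(universe), length(inject), length(dropped)))
  out
}

#' Full preprocessing pipeline
#'
#' Runs, in fixed order: optional probe collapse, log2 with cutoff,
#' per-sample standardization, alignment to the pathway universe.
#'
#' @param values Numeric matrix. Either genes x samples intensities (default
#'   orientation) or probes x samples with `probe_to_gene` supplied.
#' @param labels Named character vector or data.frame (`sample_id`, `label`);
#'   samples with labels outside `class_names` are excluded.
#' @param sets A [gene_set_collection()] defining the universe.
#' @param class_names Length-2 character vector of retained class labels.
#' @param probe_to_gene Optional probe -> gene map triggering probe collapse.
#' @param cutoff Log2 cutoff, default 1.
#' @return Aligned, standardized `expression_dataset`.
#' @export
preprocess_expression <- function(values, labels, sets, class_names,
                                  probe_to_gene = NULL, cutoff = 1) {
  if (!is.null(probe_to_gene)) {
    values <- collapse_probes(values, probe_to_gene)
  }
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  keep <- names(labels)[labels %in% class_names]
  missing_samples <- setdiff(keep, colnames(values))
  if (length(missing_samples) > 0) {
    stop("labeled samples absent from the expression table: ",
         paste(head(missing_samples, 5), collapse = ", "))
  }
  excluded <- sum(!(labels %in% class_names))
  if (excluded > 0) {
    message(sprintf("excluded %d samples with labels outside {%s}",
                    excluded, paste(class_names, collapse = ", ")))
  }
  x <- t(values[, keep, drop = FALSE])            # samples x genes
  x <- log2_with_cutoff(x, cutoff = cutoff)
  x <- standardize_per_sample(x)
  ds <- expression_dataset(x, labels[keep], class_names)
  align_to_universe(ds, sets)
}

#' Read a gene-by-sample expression TSV
#'
#' First column is the gene (or probe) id, remaining columns are samples.
#'
#' @param path TSV path.
#' @param samples_as_rows If `TRUE` the file is samples x genes and is
#'   transposed on read.
#' @return Numeric matrix, genes (or probes) x samples.
#' @export
read_expression_tsv <- function(path, samples_as_rows = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (samples_as_rows) m <- t(m)
  m
}

#' Read a sample-label TSV (`sample_id`, `label`)
#' @param path TSV path with a header row.
#' @return Named character vector: sample id -> label.
#' @export
read_labels_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   quote = "")
  setNames(df[[2]], df[[1]])
}

#' Write an expression matrix as TSV (genes x samples)
#' @param values genes x samples matrix.
#' @param path Output path.
#' @param id_col Name for the id column, default `"gene_id"`.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(values, path, id_col = "gene_id") {
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
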