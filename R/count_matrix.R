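#' Construct a single-cell count matrix with cell metadata
#'
#' The central container of the package: a genes x cells non-negative
#' expression matrix (stored sparse) together with a cell-metadata table.
#' Genes are rows, cells are columns — the Matrix Market single-cell
#' convention used throughout.
#'
#' @param values genes x cells numeric matrix (dense or `Matrix` sparse),
#'   non-negative. Non-integer values are accepted (normalized data is
#'   allowed downstream) with a warning when `warn_nonint = TRUE`.
#' @param gene_ids character vector of unique gene identifiers (rows).
#'   Defaults to `rownames(values)`.
#' @param cell_ids character vector of unique cell identifiers (columns).
#'   Defaults to `colnames(values)`.
#' @param cell_meta data.frame keyed by `cell_id` with columns such as
#'   `batch`, `donor`, `timepoint`, `condition`, `cell_type`. Must cover
#'   every cell id. If `NULL`, a minimal table with just `cell_id` is built.
#' @param warn_nonint warn when values are not integers.
#' @return an object of class `count_matrix`: a list with elements `values`
#'   (a `dgCMatrix`), `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values), cell_meta = NULL,
                         warn_nonint = TRUE) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop_invalid("gene_ids/cell_ids", "gene and cell identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stop_invalid("gene_ids", "duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop_invalid("cell_ids", "duplicate cell identifiers")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids)) {
    stop_invalid("values", sprintf(
      "matrix is %d x %d but %d gene ids and %d cell ids were given",
      nrow(values), ncol(values), length(gene_ids), length(cell_ids)))
  }
  values <- as(as(values, "CsparseMatrix"), "generalMatrix")
  if (any(values@x < 0)) stop_invalid("values", "negative entries found")
  if (warn_nonint && length(values@x) && any(values@x != round(values@x))) {
    warning("count matrix has non-integer values; treating as normalized expression")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta)) {
    stop_invalid("cell_meta", "must contain a `cell_id` column")
  }
  cell_meta$cell_id <- as.character(cell_meta$cell_id)
  missing <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(missing)) {
    stop_invalid("cell_meta", sprintf("does not cover %d cell ids (e.g. %s)",
                                      length(missing), missing[1L]))
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              length(x$gene_ids), length(x$cell_ids)))
  meta_cols <- setdiff(names(x$cell_meta), "cell_id")
  if (length(meta_cols)) cat("  cell_meta:", paste(meta_cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Subset a count matrix by genes and/or cells
#'
#' @param x a `count_matrix`.
#' @param genes gene ids or indices (optional).
#' @param cells cell ids or indices (optional).
#' @return a `count_matrix` restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  meta <- x$cell_meta[match(colnames(v), x$cell_meta$cell_id), , drop = FALSE]
  count_matrix(v, cell_meta = meta, warn_nonint = FALSE)
}

#' Construct a gene set
#'
#' An ordered list of unique gene identifiers with optional non-negative
#' weights, used for modules, programs' top genes and annotation categories.
#'
#' @param genes character vector of gene identifiers; duplicates are removed
#'   (first occurrence kept) with a warning.
#' @param name label of the set.
#' @param weights optional non-negative numeric weights, one per gene.
#' @return an object of class `gene_set` with elements `name`, `genes`,
#'   `weights`.
#' @export
gene_set <- function(genes, name = "geneset", weights = NULL) {
  genes <- as.character(genes)
  if (!length(genes)) stop_invalid("genes", "gene set is empty")
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': %d duplicated genes removed",
                    name, sum(duplicated(genes))))
    keep <- !duplicated(genes)
    genes <- genes[keep]
    if (!is.null(weights)) weights <- weights[keep]
  }
  if (!is.null(weights)) {
    if (length(weights) != length(genes)) {
      stop_invalid("weights", "must have the same length as genes")
    }
    if (any(weights < 0)) stop_invalid("weights", "must be non-negative")
    weights <- as.numeric(weights)
  }
  structure(list(name = as.character(name), genes = genes, weights = weights),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> '%s': %d genes%s\n", x$name, length(x$genes),
              if (is.null(x$weights)) "" else " (weighted)"))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Coerce gene_set | character to a character vector of genes.
as_genes <- function(x) {
  if (inherits(x, "gene_set")) x$genes else as.character(x)
}
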