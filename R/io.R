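#' Read a count matrix from disk
#'
#' Two on-disk layouts are supported. `format = "mtx"` expects a Matrix
#' Market coordinate file (genes as rows) with `features.tsv` and
#' `barcodes.tsv` sidecars in the same directory, plus an optional
#' `metadata.tsv` cell-metadata table. `format = "tsv"` expects a dense
#' tab-separated table with gene ids in the first column and cell ids as
#' header; set `orientation = "cells_by_genes"` if the table is transposed
#' (the reader never guesses).
#'
#' @param path for `mtx`, the directory (or the `.mtx` file) containing
#'   `matrix.mtx`, `features.tsv`, `barcodes.tsv`; for `tsv`, the matrix file.
#' @param format `"mtx"` or `"tsv"`.
#' @param meta_path optional path to a cell-metadata TSV with a `cell_id`
#'   column; for `mtx` defaults to `metadata.tsv` next to the matrix when
#'   present.
#' @param orientation for `tsv` only: `"genes_by_cells"` (default) or
#'   `"cells_by_genes"`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("mtx", "tsv"), meta_path = NULL,
                              orientation = c("genes_by_cells", "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(dir, "matrix.mtx") else path
    feats_f <- file.path(dir, "features.tsv")
    bars_f <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, feats_f, bars_f)) {
      if (!file.exists(f)) stop(sprintf("file not found: %s", f), call. = FALSE)
    }
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    feats <- readLines(feats_f)
    feats <- vapply(strsplit(feats, "\t", fixed = TRUE), `[`, "", 1L)
    bars <- readLines(bars_f)
    if (length(feats) != nrow(m) || length(bars) != ncol(m)) {
      stop(sprintf(
        "matrix is %d x %d but features.tsv has %d rows and barcodes.tsv has %d rows",
        nrow(m), ncol(m), length(feats), length(bars)), call. = FALSE)
    }
    rownames(m) <- feats
    colnames(m) <- bars
    if (is.null(meta_path)) {
      cand <- file.path(dir, "metadata.tsv")
      if (file.exists(cand)) meta_path <- cand
    }
  } else {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- ids
    if (orientation == "cells_by_genes") m <- t(m)
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  }
  cm <- count_matrix(m, cell_meta = meta)
  message(sprintf("read_count_matrix: %d genes x %d cells from %s",
                  nrow(cm$values), ncol(cm$values), path))
  cm
}

#' Write a count matrix to disk
#'
#' Inverse of [read_count_matrix()]: `write` followed by `read` restores
#' identical values, identifiers and metadata.
#'
#' @param x a [count_matrix()].
#' @param path output directory (`mtx`) or file (`tsv`).
#' @param format `"mtx"` (matrix.mtx + features.tsv + barcodes.tsv +
#'   metadata.tsv) or `"tsv"` (dense genes x cells table; metadata written
#'   next to it as `<path>.metadata.tsv`).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("mtx", "tsv")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(x$values, file.path(path, "matrix.mtx"))
    writeLines(x$gene_ids, file.path(path, "features.tsv"))
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
    write.table(x$cell_meta, file.path(path, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = x$gene_ids,
                      as.matrix(x$values), check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(x$cell_meta, paste0(path, ".metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Gene order is preserved; duplicate genes within a set are
#' removed with a warning; an empty set is an error.
#'
#' @param path GMT file.
#' @return a named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop(sprintf("GMT set '%s' is empty", parts[1L]), call. = FALSE)
    }
    gene_set(parts[-(1:2)], name = parts[1L])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  message(sprintf("read_gene_sets: %d sets from %s", length(sets), path))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set()] or list of them.
#' @param path output file.
#' @param description description field (second GMT column), recycled.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
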