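#' Rank-based per-cell module score (Mann-Whitney U construction)
#'
#' For each cell, all genes are ranked by decreasing expression (ties get
#' average ranks); ranks beyond `rmax` are capped at `rmax + 1`. With `n`
#' signature genes present and rank-sum `Rs`, the statistic
#' `U' = Rs - n(n+1)/2` is normalized to `score = 1 - U'/(n * rmax)` and
#' clipped to \[0, 1\]: 1 when the signature occupies the top ranks, ~0 when
#' it sits below `rmax`. Being rank-based, the score is invariant under any
#' strictly monotone transform of a cell's expression vector.
#'
#' Signature genes absent from the dataset are dropped (with a message);
#' if fewer than half are present the call errors, listing the missing
#' genes — applying a module across species by symbol overlap is explicit,
#' never silent.
#'
#' @param counts a [count_matrix()] (raw or normalized; ranks only).
#' @param signature a [gene_set()] or character vector.
#' @param rmax maximum considered rank (default 1500).
#' @return a `score_vector`: named numeric per cell in \[0, 1\], with
#'   attributes `unit = "ucell"`, `signature`, `n_genes_used`.
#' @export
ucell_score <- function(counts, signature, rmax = 1500L) {
  stopifnot(inherits(counts, "count_matrix"))
  sig <- unique(as_genes(signature))
  rmax <- check_count(rmax, "rmax")
  present <- intersect(sig, counts$gene_ids)
  if (length(present) < length(sig) / 2) {
    stop(sprintf("only %d/%d signature genes present; missing: %s",
                 length(present), length(sig),
                 paste(setdiff(sig, counts$gene_ids), collapse = ", ")),
         call. = FALSE)
  }
  if (length(present) < length(sig)) {
    message(sprintf("ucell_score: %d/%d signature genes present, rest dropped",
                    length(present), length(sig)))
  }
  if (rmax < length(present)) stop_invalid("rmax", "smaller than the signature size")
  mat <- as.matrix(counts$values)
  n <- length(present)
  sig_idx <- match(present, rownames(mat))
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    r <- rank(-mat[, j], ties.method = "average")
    r[r > rmax] <- rmax + 1
    rs <- sum(r[sig_idx])
    u <- rs - n * (n + 1) / 2
    min(max(1 - u / (n * rmax), 0), 1)
  }, 0)
  structure(setNames(scores, counts$cell_ids), unit = "ucell",
            signature = if (inherits(signature, "gene_set")) signature$name else "signature",
            n_genes_used = n, class = "score_vector")
}

#' Bulk per-sample mean-z module score
#'
#' Z-scores each module gene across samples, then averages the z-scores of
#' the module genes within each sample — the standard bulk-tissue module
#' score used to stratify patients. Genes with zero cross-sample SD are
#' dropped with a warning; if all module genes are degenerate the call
#' errors.
#'
#' @param expr genes x samples numeric matrix (log-scale expression).
#' @param signature a [gene_set()] or character vector.
#' @return a `score_vector`: named numeric per sample (mean-z units,
#'   unbounded), attribute `unit = "mean_z"`.
#' @export
bulk_module_score <- function(expr, signature) {
  if (ncol(expr) < 2L) stop("mean-z scoring needs >= 2 samples", call. = FALSE)
  sig <- unique(as_genes(signature))
  present <- intersect(sig, rownames(expr))
  if (!length(present)) stop("no signature genes present in the matrix", call. = FALSE)
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (all(degenerate)) {
    stop("all module genes have zero cross-sample SD; z-scores undefined",
         call. = FALSE)
  }
  if (any(degenerate)) {
    warning(sprintf("dropping %d zero-SD module genes", sum(degenerate)))
    sub <- sub[!degenerate, , drop = FALSE]
    sds <- sds[!degenerate]
  }
  z <- (sub - rowMeans(sub)) / sds
  structure(colMeans(z), unit = "mean_z",
            signature = if (inherits(signature, "gene_set")) signature$name else "signature",
            n_genes_used = nrow(sub), class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %d values (%s), signature '%s'\n",
              length(x), attr(x, "unit"), attr(x, "signature")))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Write a score vector as TSV with metadata join columns
#'
#' @param scores a `score_vector`.
#' @param path output TSV.
#' @param meta optional metadata data.frame with a key column matching the
#'   score names (`cell_id` or `sample_id`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, meta = NULL) {
  key <- if (attr(scores, "unit") == "ucell") "cell_id" else "sample_id"
  tab <- data.frame(id = names(scores), score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  names(tab)[1L] <- key
  if (!is.null(meta) && key %in% names(meta)) {
    tab <- merge(tab, meta, by = key, sort = FALSE)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
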