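#' Configuration for per-batch program discovery
#'
#' @param n_top_genes overdispersed genes used as discovery input
#'   (default 2000).
#' @param n_replicates number of NMF replicates pooled into the consensus
#'   (default 200).
#' @param k_range inclusive range of program counts to explore
#'   (default 7:14).
#' @param density_filter_quantile fraction of pooled replicate components
#'   discarded as local-density outliers before clustering (default 0.25).
#' @param knn_fraction fraction of `n_replicates` giving the neighbourhood
#'   size of the density filter (default 0.3).
#' @param max_iter,tol multiplicative-update iteration cap and relative
#'   objective-change tolerance.
#' @param seed mandatory integer seed.
#' @return a `discovery_config` list.
#' @export
discovery_config <- function(n_top_genes = 2000L, n_replicates = 200L,
                             k_range = 7:14, density_filter_quantile = 0.25,
                             knn_fraction = 0.3, max_iter = 200L, tol = 1e-4,
                             seed = 1L) {
  cfg <- list(
    n_top_genes = check_count(n_top_genes, "n_top_genes"),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    k_range = sort(unique(as.integer(k_range))),
    density_filter_quantile = check_fraction(density_filter_quantile,
                                             "density_filter_quantile",
                                             0, 1, open_lo = FALSE, open_hi = TRUE),
    knn_fraction = check_fraction(knn_fraction, "knn_fraction"),
    max_iter = check_count(max_iter, "max_iter"),
    tol = check_fraction(tol, "tol", 0, Inf),
    seed = check_count(seed, "seed", min = 0L))
  if (any(cfg$k_range < 1L) || any(cfg$k_range >= cfg$n_top_genes)) {
    stop_invalid("k_range", "must lie within [1, n_top_genes)")
  }
  structure(cfg, class = "discovery_config")
}

# Per-gene unit-variance scaling (no centering, so nonnegativity is
# preserved); zero-variance genes are dropped with a warning.
scale_gene_variance <- function(mat) {
  n <- ncol(mat)
  mu <- Matrix::rowSums(mat) / n
  ex2 <- Matrix::rowSums(mat^2) / n
  v <- pmax((ex2 - mu^2) * n / (n - 1), 0)
  keep <- v > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance genes before NMF", sum(!keep)))
  }
  mat <- mat[keep, , drop = FALSE]
  mat / sqrt(v[keep])
}

#' Consensus non-negative matrix factorization at a fixed K
#'
#' Runs NMF (multiplicative updates, Frobenius objective) `n_replicates`
#' times with distinct seeds on the per-gene variance-scaled matrix, pools
#' the unit-L2-normalized gene spectra of all replicates, discards the
#' locally sparse fraction (components whose mean distance to their nearest
#' neighbours is largest), clusters the survivors into K groups with
#' k-means, and takes the component-wise median of each cluster as the
#' consensus spectrum. Usages are refit by nonnegative least squares.
#' `stability` is the mean silhouette width of the replicate-component
#' clustering (1 by convention at K = 1); `error` is the Frobenius norm of
#' the residual of the consensus fit on the scaled matrix.
#'
#' @param counts a [count_matrix()] or genes x cells matrix, already
#'   restricted to the discovery genes (see [select_overdispersed()]).
#' @param K number of programs.
#' @param config a [discovery_config()].
#' @return a `program_set`: list with `K`, `spectra` (K x genes, unit-L2
#'   rows), `usages` (cells x K), `stability`, `error`,
#'   `n_replicates_used`, `config`.
#' @export
consensus_nmf <- function(counts, K, config = discovery_config()) {
  mat <- if (inherits(counts, "count_matrix")) counts$values else counts
  K <- check_count(K, "K")
  stopifnot(inherits(config, "discovery_config"))
  scaled <- scale_gene_variance(mat)
  V <- Matrix::t(scaled)  # cells x genes
  R <- config$n_replicates
  seeds <- derive_seeds(config$seed, R)
  fits <- lapply(seq_len(R), function(r) {
    nmf_fit(V, K, max_iter = config$max_iter, tol = config$tol, seed = seeds[r])
  })
  finite <- vapply(fits, `[[`, TRUE, "finite")
  if (any(!finite)) {
    warning(sprintf("dropping %d non-convergent NMF replicates", sum(!finite)))
  }
  fits <- fits[finite]
  if (length(fits) < R / 2) {
    stop("fewer than half of the NMF replicates converged", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(fits, function(f) normalize_rows_l2(f$S)))
  consensus <- consensus_from_pool(pooled, K, config, n_rep = length(fits))
  usages <- refit_usages_nnls(V, consensus$spectra)
  rownames(usages) <- colnames(mat)
  colnames(usages) <- rownames(consensus$spectra)
  resid <- as.matrix(V) - usages %*% consensus$spectra
  structure(list(K = K, spectra = consensus$spectra, usages = usages,
                 stability = consensus$stability,
                 error = sqrt(sum(resid^2)),
                 n_replicates_used = length(fits), config = config),
            class = "program_set")
}

# Density-filter the pooled replicate spectra, k-means them into K groups
# and return consensus spectra + silhouette stability. On an empty-cluster
# failure the filter is relaxed once (no filtering), then it errors.
consensus_from_pool <- function(pooled, K, config, n_rep) {
  knn_k <- max(1L, min(ceiling(config$knn_fraction * n_rep), nrow(pooled) - 1L))
  run <- function(keep_idx) {
    spectra_pool <- pooled[keep_idx, , drop = FALSE]
    if (nrow(spectra_pool) < K) stop("empty cluster", call. = FALSE)
    km <- with_seed(config$seed, kmeans(spectra_pool, centers = K,
                                        nstart = 10L, iter.max = 50L))
    if (any(tabulate(km$cluster, K) == 0L)) stop("empty cluster", call. = FALSE)
    spectra <- t(vapply(seq_len(K), function(k) {
      apply(spectra_pool[km$cluster == k, , drop = FALSE], 2L, median)
    }, numeric(ncol(spectra_pool))))
    if (K == 1L) spectra <- matrix(spectra, nrow = 1L)
    spectra <- normalize_rows_l2(spectra)
    # order programs by decreasing cluster size for a stable labelling
    ord <- order(-tabulate(km$cluster, K))
    spectra <- spectra[ord, , drop = FALSE]
    dimnames(spectra) <- list(sprintf("P%d", seq_len(K)), colnames(pooled))
    stability <- if (K == 1L) 1 else {
      sil <- cluster::silhouette(km$cluster, dist(spectra_pool))
      mean(sil[, "sil_width"])
    }
    list(spectra = spectra, stability = stability)
  }
  d <- as.matrix(dist(pooled))
  mean_knn <- apply(d, 1L, function(row) mean(sort(row)[1L + seq_len(knn_k)]))
  thresh <- quantile(mean_knn, 1 - config$density_filter_quantile, type = 7)
  keep <- which(mean_knn <= thresh)
  tryCatch(run(keep), error = function(e) {
    if (!grepl("empty cluster", conditionMessage(e))) stop(e)
    warning("empty consensus cluster after density filtering; retrying unfiltered")
    tryCatch(run(seq_len(nrow(pooled))), error = function(e2) {
      stop("consensus clustering failed even without density filtering",
           call. = FALSE)
    })
  })
}

#' @export
print.program_set <- function(x, ...) {
  cat(sprintf("<program_set> K = %d over %d genes x %d cells; stability %.3f, error %.3f\n",
              x$K, ncol(x$spectra), nrow(x$usages), x$stability, x$error))
  invisible(x)
}

#' Choose the number of programs by the stability/error trade-off
#'
#' Computes a [consensus_nmf()] per K in `config$k_range` and applies the
#' default rule: among K whose reconstruction error is within 5% of the
#' range minimum, pick the one with maximal stability (ties broken toward
#' smaller K). The full per-K table is returned so the classical visual
#' criterion (error minimal, stability maximal) can also be applied by eye.
#'
#' @param counts a [count_matrix()] or matrix restricted to discovery genes.
#' @param config a [discovery_config()].
#' @param error_band relative error band for the selection rule
#'   (default 0.05).
#' @return list with `K` (chosen), `metrics` (data.frame K, stability,
#'   error), `programs` (the `program_set` at the chosen K).
#' @export
select_k <- function(counts, config = discovery_config(), error_band = 0.05) {
  stopifnot(inherits(config, "discovery_config"))
  if (!length(config$k_range)) stop_invalid("k_range", "empty")
  fits <- list()
  for (K in config$k_range) {
    fits[[as.character(K)]] <- tryCatch(consensus_nmf(counts, K, config),
                                        error = function(e) e)
  }
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok)) stop("all K values failed during consensus NMF", call. = FALSE)
  metrics <- data.frame(
    K = config$k_range[ok],
    stability = vapply(fits[ok], `[[`, 0, "stability"),
    error = vapply(fits[ok], `[[`, 0, "error"))
  rownames(metrics) <- NULL
  in_band <- metrics$error <= min(metrics$error) * (1 + error_band)
  cand <- metrics[in_band, , drop = FALSE]
  cand <- cand[order(-cand$stability, cand$K), , drop = FALSE]
  chosen <- cand$K[1L]
  list(K = chosen, metrics = metrics,
       programs = fits[[as.character(chosen)]])
}
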