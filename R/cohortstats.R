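# Library-size normalization used by the correlation machinery:
# counts scaled to the median library size, then log1p. Correlations are
# computed on this scale so library-size variation does not induce
# spurious positive gene-gene correlation.
lognormalize <- function(mat) {
  libs <- Matrix::colSums(mat)
  libs[libs == 0] <- 1
  target <- median(libs)
  log1p(Matrix::t(Matrix::t(mat) * (target / libs)))
}

# Mean pairwise Pearson correlation (across cells) among a set of genes.
# Zero-variance pairs yield NA and are skipped; their count is returned.
mean_pairwise_cor <- function(mat_cells_by_genes) {
  C <- suppressWarnings(cor(mat_cells_by_genes))
  off <- C[upper.tri(C)]
  list(r = mean(off, na.rm = TRUE), n_skipped = sum(is.na(off)))
}

#' Correlation validation of a module against a random-gene null
#'
#' Independently validates that module genes are co-expressed: per cell
#' type, the mean pairwise Pearson correlation (across cells, on
#' log-normalized expression) among module genes is compared with the same
#' statistic for `n_random` equal-size random draws from expressed genes.
#' The empirical p-value is `(1 + #{null >= observed}) / (n_random + 1)`.
#'
#' @param counts a [count_matrix()] with a `cell_type` metadata column.
#' @param signature a [gene_set()] or character vector (>= 2 genes).
#' @param n_random number of random draws (default 1000).
#' @param seed integer seed.
#' @param min_cells cell types with fewer cells are skipped.
#' @return a `correlation_null` list: `observed` (named per cell type),
#'   `null` (n_random x cell types matrix), `p` (named), `n_skipped_pairs`.
#' @export
correlation_null_test <- function(counts, signature, n_random = 1000L,
                                  seed = 1L, min_cells = 3L) {
  stopifnot(inherits(counts, "count_matrix"))
  sig <- intersect(unique(as_genes(signature)), counts$gene_ids)
  if (length(sig) < 2L) stop("signature needs >= 2 genes present", call. = FALSE)
  n_random <- check_count(n_random, "n_random")
  norm <- lognormalize(counts$values)
  types <- sort(unique(counts$cell_meta$cell_type))
  keep <- vapply(types, function(ct) {
    sum(counts$cell_meta$cell_type == ct) >= min_cells
  }, TRUE)
  if (!all(keep)) warning(sprintf("skipping %d cell types with < %d cells",
                                  sum(!keep), min_cells))
  types <- types[keep]
  cells_by_type <- lapply(types, function(ct) {
    which(counts$cell_meta$cell_type == ct)
  })
  names(cells_by_type) <- types
  expressed <- counts$gene_ids[Matrix::rowSums(counts$values) > 0]
  observed <- numeric(length(types))
  skipped <- 0L
  dense <- as.matrix(norm)
  for (i in seq_along(types)) {
    res <- mean_pairwise_cor(t(dense[sig, cells_by_type[[i]], drop = FALSE]))
    observed[i] <- res$r
    skipped <- skipped + res$n_skipped
  }
  names(observed) <- types
  null <- with_seed(seed, {
    vapply(seq_len(n_random), function(d) {
      rg <- sample(expressed, length(sig))
      vapply(seq_along(types), function(i) {
        mean_pairwise_cor(t(dense[rg, cells_by_type[[i]], drop = FALSE]))$r
      }, 0)
    }, numeric(length(types)))
  })
  null <- t(matrix(null, nrow = length(types)))
  colnames(null) <- types
  p <- vapply(seq_along(types), function(i) {
    (1 + sum(null[, i] >= observed[i], na.rm = TRUE)) / (n_random + 1)
  }, 0)
  names(p) <- types
  structure(list(observed = observed, null = null, p = p,
                 n_skipped_pairs = skipped, n_random = n_random, seed = seed),
            class = "correlation_null")
}

#' Longitudinal trend of a module score
#'
#' Ordinary least squares of the per-cell module score on the timepoint
#' code tau = 0, 1, 2, ... fit separately per (cell type, condition);
#' cells are the observations. A negative slope means the score declines
#' over the timepoints. `reverse = TRUE` swaps outcome and predictor
#' (time ~ score); the sign of the reported slope is shared.
#'
#' @param scores a `score_vector` named by cell id.
#' @param cell_meta data.frame with `cell_id`, `cell_type`, `condition`,
#'   `timepoint`.
#' @param timepoints ordered timepoint labels; defaults to sorted unique.
#' @param reverse fit time ~ score instead of score ~ time.
#' @return data.frame (cell_type, condition, beta, p, n); groups with a
#'   single observed timepoint are omitted with a warning.
#' @export
trend_regression <- function(scores, cell_meta, timepoints = NULL,
                             reverse = FALSE) {
  stopifnot(all(c("cell_id", "cell_type", "condition", "timepoint") %in%
                  names(cell_meta)))
  cell_meta <- cell_meta[match(names(scores), cell_meta$cell_id), , drop = FALSE]
  timepoints <- timepoints %||% sort(unique(cell_meta$timepoint))
  tau <- match(cell_meta$timepoint, timepoints) - 1L
  if (anyNA(tau)) stop("timepoint labels not covered by `timepoints`", call. = FALSE)
  out <- list()
  dropped <- 0L
  for (ct in sort(unique(cell_meta$cell_type))) {
    for (cond in sort(unique(cell_meta$condition))) {
      idx <- which(cell_meta$cell_type == ct & cell_meta$condition == cond)
      if (!length(idx)) next
      if (length(unique(tau[idx])) < 2L) {
        dropped <- dropped + 1L
        next
      }
      y <- as.numeric(scores[idx]); x <- tau[idx]
      fit <- if (reverse) lm(x ~ y) else lm(y ~ x)
      sm <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ct, condition = cond,
        beta = unname(sm[2L, 1L]),
        p = unname(sm[2L, 4L]),
        n = length(idx), stringsAsFactors = FALSE)
    }
  }
  if (dropped) warning(sprintf("%d cell type x condition groups had a single timepoint; omitted",
                               dropped))
  do.call(rbind, out)
}

#' Permutation-resampling robustness of a two-group score difference
#'
#' Controls for unequal group sizes: each repetition subsamples `n_cells`
#' scores per group without replacement (independent fresh draws), runs a
#' two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction), adjusts the `n_perm` p-values with Benjamini-Hochberg, and
#' reports the proportion of repetitions with adjusted p below `alpha`.
#'
#' @param scores_a,scores_b numeric score vectors of the two groups.
#' @param n_cells per-group subsample size (default 200).
#' @param n_perm number of repetitions (default 5000).
#' @param alpha FDR threshold (default 0.05).
#' @param seed integer seed.
#' @return a `permutation_result` list: `proportion_significant`, `p_raw`,
#'   `p_adj`, `group_means` (n_perm x 2), and the settings.
#' @export
permutation_robustness <- function(scores_a, scores_b, n_cells = 200L,
                                   n_perm = 5000L, alpha = 0.05, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  n_perm <- check_count(n_perm, "n_perm")
  a <- as.numeric(scores_a); b <- as.numeric(scores_b)
  if (length(a) < n_cells || length(b) < n_cells) {
    small <- if (length(a) < n_cells) "first" else "second"
    stop(sprintf("%s group has %d cells, fewer than n_cells = %d",
                 small, min(length(a), length(b)), n_cells), call. = FALSE)
  }
  res <- with_seed(seed, {
    p_raw <- numeric(n_perm)
    means <- matrix(0, n_perm, 2L, dimnames = list(NULL, c("group_a", "group_b")))
    for (i in seq_len(n_perm)) {
      xa <- a[sample.int(length(a), n_cells)]
      xb <- b[sample.int(length(b), n_cells)]
      p_raw[i] <- suppressWarnings(
        wilcox.test(xa, xb, exact = FALSE)$p.value)
      means[i, ] <- c(mean(xa), mean(xb))
    }
    list(p_raw = p_raw, means = means)
  })
  p_adj <- p.adjust(res$p_raw, method = "BH")
  structure(list(proportion_significant = mean(p_adj < alpha),
                 p_raw = res$p_raw, p_adj = p_adj,
                 group_means = res$means,
                 n_cells = n_cells, n_perm = n_perm, alpha = alpha,
                 seed = seed),
            class = "permutation_result")
}

#' Two-sample Kolmogorov-Smirnov comparison of score distributions
#'
#' D is the maximum vertical distance between the two empirical CDFs; the
#' p-value is asymptotic (the null being that both samples share one
#' distribution).
#'
#' @param scores_a,scores_b numeric vectors.
#' @return list with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_compare <- function(scores_a, scores_b) {
  a <- as.numeric(scores_a); b <- as.numeric(scores_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Stratify samples by module score and compare a target gene
#'
#' Splits samples at the 25th/75th percentiles of the module score
#' (type-7 quantiles; scores tied with a boundary go to the lower stratum)
#' into low (< 25%), mid (25-75%) and high (> 75%) strata, then compares
#' the target gene's expression between strata with pairwise two-sided
#' Wilcoxon rank-sum tests.
#'
#' @param scores a `score_vector` (or named numeric) per sample.
#' @param target_expr named numeric, the target gene's expression per
#'   sample (names must cover the score names).
#' @return list with `strata` (named factor low/mid/high), `counts`,
#'   `comparisons` (data.frame a, b, W, p).
#' @export
stratify_by_module <- function(scores, target_expr) {
  s <- as.numeric(scores)
  names(s) <- names(scores)
  if (length(s) < 4L) stop("stratification needs >= 4 samples", call. = FALSE)
  if (!all(names(s) %in% names(target_expr))) {
    stop("target_expr does not cover all scored samples", call. = FALSE)
  }
  expr <- as.numeric(target_expr[names(s)])
  q <- quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  strata <- factor(ifelse(s <= q[1L], "low", ifelse(s > q[2L], "high", "mid")),
                   levels = c("low", "mid", "high"))
  counts <- table(strata)
  if (any(counts == 0L)) {
    stop("a stratum is empty after ties; more samples are needed", call. = FALSE)
  }
  pairs <- list(c("low", "mid"), c("mid", "high"), c("low", "high"))
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- suppressWarnings(wilcox.test(expr[strata == pr[2L]],
                                       expr[strata == pr[1L]], exact = FALSE))
    data.frame(a = pr[1L], b = pr[2L], W = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
  list(strata = setNames(strata, names(s)), counts = counts,
       comparisons = comparisons)
}

#' Gradient gene scan across ordered conditions
#'
#' Identifies genes with a monotone expression gradient across ordered
#' conditions coded 0, 1, 2, ...: cells of each condition are randomly
#' partitioned into `n_groups` pseudo-replicates (each of at least
#' `min_cells` cells), per-gene mean expression is computed per
#' pseudo-replicate, and an OLS of pseudo-replicate means on the condition
#' code gives slope and two-sided p per gene.
#'
#' @param counts a [count_matrix()].
#' @param condition_codes named integer vector (cell id -> code 0/1/2...).
#' @param n_groups pseudo-replicates per condition (default 10).
#' @param min_cells minimum cells per pseudo-replicate (default 50).
#' @param seed integer seed for the random partition.
#' @return data.frame (gene, slope, p, direction) sorted by p.
#' @export
gradient_gene_scan <- function(counts, condition_codes, n_groups = 10L,
                               min_cells = 50L, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  n_groups <- check_count(n_groups, "n_groups")
  min_cells <- check_count(min_cells, "min_cells")
  codes <- condition_codes[counts$cell_ids]
  if (anyNA(codes)) stop("condition_codes must cover every cell", call. = FALSE)
  conds <- sort(unique(codes))
  for (cc in conds) {
    n_c <- sum(codes == cc)
    if (floor(n_c / n_groups) < min_cells) {
      stop(sprintf(
        "condition %s has %d cells: %d groups of >= %d cells impossible (at most %d groups)",
        cc, n_c, n_groups, min_cells, floor(n_c / min_cells)), call. = FALSE)
    }
  }
  assign_groups <- with_seed(seed, {
    g <- integer(length(codes))
    for (cc in conds) {
      idx <- which(codes == cc)
      g[idx] <- sample(rep_len(seq_len(n_groups), length(idx)))
    }
    g
  })
  key <- interaction(codes, assign_groups, drop = TRUE)
  dense <- as.matrix(counts$values)
  sums <- t(rowsum(t(dense), key))          # genes x pseudo-groups
  sizes <- as.numeric(table(key)[colnames(sums)])
  means <- sweep(sums, 2L, sizes, `/`)
  x <- as.numeric(sub("\\..*$", "", colnames(means)))
  m <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- means - rowMeans(means)
  slope <- as.numeric(yc %*% xc) / sxx
  rss <- rowSums((yc - outer(slope, xc))^2)
  se <- sqrt(rss / (m - 2) / sxx)
  tstat <- ifelse(se > 0, slope / se, 0)
  p <- 2 * pt(-abs(tstat), df = m - 2)
  out <- data.frame(gene = rownames(means), slope = slope, p = p,
                    direction = ifelse(slope > 0, "up",
                                       ifelse(slope < 0, "down", "flat")),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$gene), , drop = FALSE]
}
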