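# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive each statistic from first principles and
# never call the code paths they verify.

# Rank-based module score oracle: explicit sort-based ranking with average
# ties, rank capping, rank-sum U' and the [0,1] normalization.
oracle_rank_score <- function(expr, sig_genes, rmax) {
  ord <- sort(unique(expr), decreasing = TRUE)
  r <- numeric(length(expr))
  names(r) <- names(expr)
  pos <- 1
  for (v in ord) {
    idx <- which(expr == v)
    r[idx] <- mean(seq(pos, pos + length(idx) - 1))
    pos <- pos + length(idx)
  }
  r[r > rmax] <- rmax + 1
  n <- length(sig_genes)
  u <- sum(r[sig_genes]) - n * (n + 1) / 2
  min(max(1 - u / (n * rmax), 0), 1)
}

# Two-sample KS statistic by full ECDF enumeration over the pooled grid.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Benjamini-Hochberg by the textbook step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Two-sided Fisher p by enumeration of all tables with the observed
# margins, probability-ordering rule.
oracle_fisher_p <- function(a, b, c_, d) {
  K <- a + c_        # category size
  n <- a + b         # module size
  N <- a + b + c_ + d
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- dhyper(ks, K, N - K, n)
  p_obs <- dhyper(a, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# OLS slope by the covariance/variance ratio.
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Small count matrix with block structure for discovery tests:
# `blocks` disjoint gene programs active in disjoint cell groups.
make_block_matrix <- function(n_genes_per_block = 30, n_cells_per_block = 40,
                              blocks = 3, signal = 10, noise_mean = 0.3,
                              seed = 42) {
  withr::local_seed(seed)
  G <- n_genes_per_block * blocks
  N <- n_cells_per_block * blocks
  mu <- matrix(noise_mean, G, N)
  for (b in seq_len(blocks)) {
    gi <- (b - 1) * n_genes_per_block + seq_len(n_genes_per_block)
    ci <- (b - 1) * n_cells_per_block + seq_len(n_cells_per_block)
    mu[gi, ci] <- signal
  }
  m <- matrix(rpois(G * N, mu), G, N,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("c%03d", 1:N)))
  list(counts = count_matrix(m, warn_nonint = FALSE),
       block_genes = split(sprintf("g%03d", 1:G),
                           rep(seq_len(blocks), each = n_genes_per_block)))
}

# Tiny deterministic count matrix with metadata, for scoring/stats tests.
make_toy_counts <- function(n_genes = 50, n_cells = 60, seed = 7,
                            n_types = 2) {
  withr::local_seed(seed)
  m <- matrix(rpois(n_genes * n_cells, rlnorm(n_genes, 0.5, 0.8)),
              n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  meta <- data.frame(
    cell_id = colnames(m),
    batch = "B1",
    donor = "D1",
    timepoint = rep(c("T0", "T1", "T2"), length.out = n_cells),
    condition = rep(c("stable", "rejection"), length.out = n_cells),
    cell_type = sprintf("CT%d", rep_len(rep(seq_len(n_types),
                                            each = ceiling(n_cells / n_types)),
                                        n_cells)),
    stringsAsFactors = FALSE)
  count_matrix(m, cell_meta = meta, warn_nonint = FALSE)
}

# Cohort config with all planted effects switched off (independent genes).
null_cohort_config <- function(n_genes = 500, n_cells_per_type_per_donor = 30,
                               n_celltypes = 2, n_batches = 1, seed = 1,
                               ...) {
  cohort_config(n_genes = n_genes, n_celltypes = n_celltypes,
                n_batches = n_batches, n_identity_genes = 1,
                n_module_genes = 2, identity_fc = 1, module_fc = 1,
                activity_sigma = 0, trend_effect = c(1, 1, 1),
                n_cells_per_type_per_donor = n_cells_per_type_per_donor,
                seed = seed, ...)
}
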