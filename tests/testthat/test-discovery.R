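test_that("CV2 ranking is monotone in variance at fixed mean", {
  withr::local_seed(1)
  n <- 200
  base <- matrix(rpois(50 * n, 5), 50, n)
  x <- rpois(n, 5)
  infl <- 5 + (x - 5) * sqrt(10)            # same mean, variance x10
  m <- rbind(base, calm = x, wild = infl)
  rownames(m) <- c(sprintf("g%02d", 1:50), "calm", "wild")
  f <- suppressWarnings(cv2_fit(m))
  expect_lt(f$p[f$gene == "wild"], f$p[f$gene == "calm"])
})

test_that("CV2 deviation test is calibrated on pure Poisson genes", {
  withr::local_seed(2)
  m <- matrix(rpois(2000 * 200, rlnorm(2000, 1.5, 1)), 2000, 200)
  rownames(m) <- sprintf("g%04d", 1:2000)
  f <- suppressWarnings(cv2_fit(m))
  expect_lt(abs(mean(f$p < 0.05, na.rm = TRUE) - 0.05), 0.03)
})

test_that("constant genes rank last and are never selected", {
  withr::local_seed(3)
  m <- rbind(matrix(rpois(30 * 100, 4), 30, 100),
             flat = rep(5, 100))
  rownames(m) <- c(sprintf("g%02d", 1:30), "flat")
  sel <- suppressWarnings(select_overdispersed(m, n_top = 30))
  expect_false("flat" %in% sel$genes$genes)
})

test_that("multiplicative updates never increase the Frobenius objective", {
  withr::local_seed(4)
  V <- matrix(rpois(40 * 25, 3), 40, 25)
  fit <- scmodules:::nmf_fit(V, K = 3, max_iter = 60, tol = 0,
                             seed = 9, track_objective = TRUE)
  expect_true(all(diff(fit$trace) <= 1e-8 * abs(fit$trace[-length(fit$trace)]) + 1e-8))
})

test_that("rank-1 input at K = 1 is factored exactly with stability 1", {
  withr::local_seed(5)
  u <- runif(30, 1, 3)
  v <- runif(20, 1, 3)
  m <- outer(u, v)
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:20))
  ps <- suppressWarnings(consensus_nmf(
    m, K = 1,
    config = discovery_config(n_top_genes = 30, n_replicates = 4,
                              k_range = 1:1, max_iter = 500, tol = 1e-12,
                              seed = 6)))
  scaled <- scmodules:::scale_gene_variance(m)
  rel_err <- ps$error / sqrt(sum(as.matrix(Matrix::t(scaled))^2))
  expect_lt(rel_err, 1e-6)
  expect_identical(ps$stability, 1)
  expect_equal(sqrt(sum(ps$spectra^2)), 1, tolerance = 1e-10)
})

test_that("consensus NMF recovers planted blocks and prefers the true K", {
  bl <- make_block_matrix(blocks = 3, n_genes_per_block = 20, seed = 11)
  cfg <- discovery_config(n_top_genes = 90, n_replicates = 8, k_range = 2:3,
                          max_iter = 100, tol = 1e-5, seed = 12)
  ps3 <- consensus_nmf(bl$counts, K = 3, config = cfg)
  top20 <- lapply(rownames(ps3$spectra), function(p)
    scmodules:::program_top_genes(ps3$spectra[p, ], 20))
  best <- vapply(bl$block_genes, function(bg) {
    max(vapply(top20, function(tg) jaccard(tg, bg), 0))
  }, 0)
  expect_true(all(best >= 0.9))

  ps2 <- consensus_nmf(bl$counts, K = 2, config = cfg)
  expect_lt(ps2$stability, ps3$stability)
})

test_that("consensus NMF is deterministic given its seed", {
  bl <- make_block_matrix(blocks = 2, n_genes_per_block = 15,
                          n_cells_per_block = 20, seed = 13)
  cfg <- discovery_config(n_top_genes = 30, n_replicates = 4, k_range = 2:2,
                          max_iter = 50, seed = 21)
  a <- consensus_nmf(bl$counts, K = 2, config = cfg)
  b <- consensus_nmf(bl$counts, K = 2, config = cfg)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$usages, b$usages)
  expect_identical(a$error, b$error)
})

test_that("program spectra are nonnegative unit-L2 rows and usages nonnegative", {
  bl <- make_block_matrix(blocks = 2, n_genes_per_block = 15,
                          n_cells_per_block = 20, seed = 14)
  ps <- consensus_nmf(bl$counts, K = 2,
                      config = discovery_config(n_top_genes = 30,
                                                n_replicates = 4,
                                                k_range = 2:2, seed = 3))
  expect_true(all(ps$spectra >= 0))
  expect_true(all(ps$usages >= 0))
  expect_equal(unname(sqrt(rowSums(ps$spectra^2))), rep(1, 2), tolerance = 1e-10)
})

test_that("a singleton k_range returns that K with its metrics", {
  bl <- make_block_matrix(blocks = 2, n_genes_per_block = 15,
                          n_cells_per_block = 20, seed = 15)
  res <- select_k(bl$counts, discovery_config(n_top_genes = 30,
                                              n_replicates = 4,
                                              k_range = 3:3, seed = 4))
  expect_identical(res$K, 3L)
  expect_identical(nrow(res$metrics), 1L)
  expect_s3_class(res$programs, "program_set")
})
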