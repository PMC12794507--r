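test_that("perfectly co-expressed genes get the minimal empirical p", {
  withr::local_seed(1)
  base <- make_toy_counts(n_genes = 120, n_cells = 60, seed = 4)
  m <- as.matrix(base$values)
  # duplicate one driver gene into a 5-gene perfectly correlated block
  driver <- m[1, ]
  for (i in 2:5) m[i, ] <- driver
  cm <- count_matrix(m, cell_meta = base$cell_meta, warn_nonint = FALSE)
  res <- correlation_null_test(cm, rownames(m)[1:5], n_random = 99, seed = 5)
  expect_true(all(res$observed > 0.99))
  expect_true(all(res$p == 1 / 100))
})

test_that("independent-gene signatures sit in the correlation null", {
  co <- generate_cohort(null_cohort_config(n_genes = 300,
                                           n_cells_per_type_per_donor = 25,
                                           seed = 6))
  sig <- sample(co$counts$gene_ids, 20)
  res <- correlation_null_test(co$counts, sig, n_random = 200, seed = 7)
  expect_true(all(abs(res$observed) < 0.05))
  expect_true(all(abs(colMeans(res$null)) < 0.02))
  expect_true(all(res$p > 0.05))
})

test_that("trend regression matches exact and closed-form slopes", {
  meta <- data.frame(cell_id = c("c1", "c2", "c3"), cell_type = "CT1",
                     condition = "stable", timepoint = c("T0", "T1", "T2"))
  s <- structure(setNames(c(0, 1, 2), meta$cell_id), class = "score_vector")
  tr <- suppressWarnings(trend_regression(s, meta))  # exact fit warns in summary.lm
  expect_equal(tr$beta, 1, tolerance = 1e-12)

  s0 <- structure(setNames(c(0.4, 0.4, 0.4), meta$cell_id), class = "score_vector")
  expect_equal(suppressWarnings(trend_regression(s0, meta))$beta, 0,
               tolerance = 1e-12)

  withr::local_seed(2)
  n <- 120
  meta2 <- data.frame(cell_id = sprintf("c%03d", 1:n), cell_type = "CT1",
                      condition = "stable",
                      timepoint = sample(c("T0", "T1", "T2"), n, TRUE))
  y <- rnorm(n)
  s2 <- setNames(y, meta2$cell_id)
  tau <- match(meta2$timepoint, c("T0", "T1", "T2")) - 1
  expect_equal(trend_regression(s2, meta2)$beta, oracle_slope(tau, y),
               tolerance = 1e-10)
})

test_that("trend regression recovers the planted decline in rejection only", {
  cfg <- cohort_config(n_genes = 400, n_celltypes = 2, n_identity_genes = 20,
                       n_module_genes = 30, n_cells_per_type_per_donor = 60,
                       trend_effect = c(1.0, 0.6, 0.4), n_batches = 1,
                       seed = 8)
  co <- generate_cohort(cfg)
  scores <- ucell_score(co$counts, co$truth$batch_module_genes$B1,
                        rmax = nrow(co$counts$values))
  tr <- trend_regression(scores, co$counts$cell_meta)
  rej <- tr[tr$condition == "rejection", ]
  sta <- tr[tr$condition == "stable", ]
  expect_true(all(rej$beta < 0))
  expect_true(all(rej$p < 0.01))
  expect_true(all(abs(sta$beta) < abs(rej$beta)))
})

test_that("identical groups yield no significant resampling repetitions", {
  x <- rnorm(300)
  pr <- permutation_robustness(x, x, n_cells = 100, n_perm = 50, seed = 1)
  expect_identical(pr$proportion_significant, 0)
  expect_true(all(pr$p_adj >= pr$p_raw))
})

test_that("resampling robustness errors on undersized groups", {
  expect_error(permutation_robustness(rnorm(50), rnorm(300), n_cells = 100,
                                      n_perm = 10),
               "first group has 50")
})

test_that("BH adjustment equals the brute-force oracle inside the procedure", {
  withr::local_seed(3)
  a <- rnorm(400)
  b <- rnorm(400, 0.15)
  pr <- permutation_robustness(a, b, n_cells = 150, n_perm = 200, seed = 9)
  expect_equal(pr$p_adj, oracle_bh(pr$p_raw), tolerance = 1e-12)
  expect_identical(pr$proportion_significant,
                   mean(oracle_bh(pr$p_raw) < 0.05))
})

test_that("robustness proportion grows with the planted effect", {
  withr::local_seed(4)
  base <- rnorm(1000)
  props <- vapply(c(0, 0.3, 1), function(d) {
    permutation_robustness(base, rnorm(1000, d), n_cells = 150, n_perm = 300,
                           seed = 10)$proportion_significant
  }, 0)
  expect_true(all(diff(props) >= 0))
  expect_identical(props[[3]], 1)
})

test_that("KS comparison matches the ECDF enumeration oracle", {
  expect_identical(ks_compare(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_identical(ks_compare(1:5, 11:15)$D, 1)
  expect_identical(ks_compare(c(1, 3), c(2, 4))$D, 0.5)
  withr::local_seed(5)
  for (i in 1:50) {
    a <- round(rnorm(sample(3:12, 1)), 1)
    b <- round(rnorm(sample(3:12, 1), sample(0:1, 1)), 1)
    expect_equal(ks_compare(a, b)$D, oracle_ks_D(a, b), tolerance = 1e-12)
  }
})

test_that("quartile stratification splits 8 equal-spaced scores 2/4/2", {
  s <- setNames(1:8, sprintf("s%d", 1:8))
  tg <- setNames(rnorm(8), names(s))
  st <- stratify_by_module(s, tg)
  expect_identical(as.integer(st$counts), c(2L, 4L, 2L))
  expect_error(stratify_by_module(s[1:3], tg[1:3]), ">= 4 samples")
})

test_that("stratification detects a ligand coupled to the module score", {
  b <- generate_bulk(bulk_config(n_samples_per_group = 50, module_shift = 1,
                                 seed = 12, n_genes = 200, n_module_genes = 20))
  sc <- bulk_module_score(b$expr, b$truth$module_genes)
  tg <- setNames(b$expr[b$truth$ligand_gene, ], colnames(b$expr))
  st <- stratify_by_module(sc, tg)
  lh <- st$comparisons[st$comparisons$a == "low" & st$comparisons$b == "high", ]
  expect_lt(lh$p, 0.05)
  expect_gt(mean(tg[st$strata == "high"]), mean(tg[st$strata == "low"]))
})

test_that("gradient scan finds planted gradients and validates group sizes", {
  withr::local_seed(6)
  n_per <- 200
  codes <- rep(0:2, each = n_per)
  m <- rbind(grad = rpois(3 * n_per, lambda = 2 + codes),
             matrix(rpois(30 * 3 * n_per, 2), 30))
  rownames(m) <- c("grad", sprintf("g%02d", 1:30))
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  cm <- count_matrix(m, warn_nonint = FALSE)
  codes <- setNames(codes, colnames(m))
  res <- gradient_gene_scan(cm, codes, n_groups = 4, min_cells = 50, seed = 13)
  g <- res[res$gene == "grad", ]
  expect_gt(g$slope, 0)
  expect_lt(g$p, 0.05)
  expect_identical(g$direction, "up")
  expect_error(gradient_gene_scan(cm, codes, n_groups = 5, min_cells = 50),
               "at most 4 groups")
})
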