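test_that("rank score hits its closed-form anchor points", {
  # signature occupying the top ranks scores exactly 1
  expr <- c(g1 = 10, g2 = 9, g3 = 1, g4 = 2, g5 = 3)
  cm <- count_matrix(matrix(expr, 5, 1, dimnames = list(names(expr), "c1")),
                     warn_nonint = FALSE)
  expect_identical(as.numeric(ucell_score(cm, c("g1", "g2"), rmax = 5)), 1)

  # the worked 5-gene example: signature at ranks 2 and 4 of 5, rmax 5
  expr2 <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
  cm2 <- count_matrix(matrix(expr2, 5, 1, dimnames = list(names(expr2), "c1")),
                      warn_nonint = FALSE)
  s <- as.numeric(ucell_score(cm2, c("g2", "g4"), rmax = 5))
  expect_equal(s, 0.7, tolerance = 1e-12)
  expect_equal(s, oracle_rank_score(expr2, c("g2", "g4"), rmax = 5),
               tolerance = 1e-12)

  # all signature genes beyond rmax: capped ranks give (n-1)/(2*rmax)
  n_genes <- 40
  expr3 <- setNames(seq(n_genes, 1), sprintf("g%02d", 1:n_genes))
  cm3 <- count_matrix(matrix(expr3, n_genes, 1,
                             dimnames = list(names(expr3), "c1")),
                      warn_nonint = FALSE)
  sig <- sprintf("g%02d", (n_genes - 1):n_genes)  # the two lowest-ranked
  s3 <- as.numeric(ucell_score(cm3, sig, rmax = 20))
  expect_equal(s3, (2 - 1) / (2 * 20), tolerance = 1e-12)
})

test_that("rank score agrees with the brute-force oracle on random cells", {
  withr::local_seed(1)
  cm <- make_toy_counts(n_genes = 80, n_cells = 25)
  sig <- sample(cm$gene_ids, 10)
  s <- ucell_score(cm, sig, rmax = 50)
  for (j in seq_len(ncol(cm$values))) {
    expr <- setNames(as.numeric(cm$values[, j]), cm$gene_ids)
    expect_equal(as.numeric(s[j]), oracle_rank_score(expr, sig, rmax = 50),
                 tolerance = 1e-12)
  }
})

test_that("rank score is invariant under strictly monotone transforms", {
  withr::local_seed(2)
  cm <- make_toy_counts(n_genes = 60, n_cells = 10)
  sig <- sample(cm$gene_ids, 8)
  base <- ucell_score(cm, sig, rmax = 40)
  for (f in list(function(x) 3 * x + 2, function(x) x^3,
                 function(x) exp(x / 10))) {
    tr <- count_matrix(f(as.matrix(cm$values)), cell_meta = cm$cell_meta,
                       warn_nonint = FALSE)
    expect_equal(as.numeric(ucell_score(tr, sig, rmax = 40)),
                 as.numeric(base), tolerance = 1e-12)
  }
})

test_that("random-signature scores center on the permuted-gene null", {
  withr::local_seed(3)
  cm <- make_toy_counts(n_genes = 200, n_cells = 80, seed = 11)
  obs <- mean(replicate(20, {
    mean(ucell_score(cm, sample(cm$gene_ids, 15), rmax = 150))
  }))
  perm <- mean(replicate(20, {
    shuf <- cm
    shuf$values <- cm$values[sample(nrow(cm$values)), , drop = FALSE]
    rownames(shuf$values) <- cm$gene_ids
    mean(ucell_score(shuf, sample(cm$gene_ids, 15), rmax = 150))
  }))
  expect_lt(abs(obs - perm), 0.05)
})

test_that("missing signature genes are dropped explicitly or error past 50%", {
  cm <- make_toy_counts(n_genes = 30, n_cells = 5)
  sig <- c(cm$gene_ids[1:4], "ABSENT1")
  expect_message(s <- ucell_score(cm, sig, rmax = 20), "4/5")
  expect_length(s, 5L)
  expect_error(ucell_score(cm, c(cm$gene_ids[1], "A1", "A2", "A3"), rmax = 20),
               "A2")
})

test_that("bulk mean-z score matches manual arithmetic", {
  expr <- matrix(c(1, 2, 3, 4,
                   2, 4, 6, 8,
                   5, 5, 7, 7), 3, 4, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), sprintf("s%d", 1:4)))
  sc <- bulk_module_score(expr, c("gA", "gB", "gC"))
  manual <- colMeans((expr - rowMeans(expr)) / apply(expr, 1, sd))
  expect_equal(as.numeric(sc), as.numeric(manual), tolerance = 1e-12)
  expect_equal(sum(sc), 0, tolerance = 1e-10)  # z-construction centers rows

  # single module gene: the score is that gene's z-score vector
  sc1 <- bulk_module_score(expr, "gB")
  expect_equal(as.numeric(sc1),
               as.numeric((expr["gB", ] - mean(expr["gB", ])) / sd(expr["gB", ])),
               tolerance = 1e-12)
})

test_that("degenerate bulk inputs take the documented error/warning paths", {
  flat <- matrix(3, 3, 4, dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  expect_error(bulk_module_score(flat, c("a", "b")), "zero cross-sample SD")
  mixed <- flat
  mixed["a", ] <- 1:4
  expect_warning(sc <- bulk_module_score(mixed, c("a", "b")), "zero-SD")
  expect_length(sc, 4L)
  expect_error(bulk_module_score(flat[, 1, drop = FALSE], "a"), ">= 2 samples")
})
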