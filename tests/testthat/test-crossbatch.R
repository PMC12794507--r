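# Build a minimal program_set around given top-gene lists: weights are a
# decreasing ramp over the listed genes inside a shared gene universe.
fake_program_set <- function(top_lists, universe) {
  K <- length(top_lists)
  spectra <- matrix(0, K, length(universe),
                    dimnames = list(sprintf("P%d", seq_len(K)), universe))
  for (k in seq_len(K)) {
    genes <- top_lists[[k]]
    spectra[k, genes] <- rev(seq_along(genes)) + 10
  }
  spectra <- spectra + matrix(runif(length(spectra), 0, 1e-3), K)
  spectra <- spectra / sqrt(rowSums(spectra^2))
  structure(list(K = K, spectra = spectra,
                 usages = matrix(1, 2, K), stability = 1, error = 0),
            class = "program_set")
}

test_that("jaccard similarity matches its set definition", {
  expect_identical(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_identical(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_identical(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_identical(jaccard(character(), character()), 0)
})

test_that("jaccard is symmetric, bounded, and 1 iff equal (property)", {
  withr::local_seed(1)
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:25) {
    a <- sample(pool, sample(0:12, 1))
    b <- sample(pool, sample(1:12, 1))
    s <- jaccard(a, b)
    expect_identical(s, jaccard(b, a))
    expect_true(s >= 0 && s <= 1)
    if (length(a)) expect_identical(s == 1, setequal(a, b))
  }
})

test_that("identical per-batch programs collapse to one full-coverage cluster", {
  universe <- sprintf("g%03d", 1:300)
  shared <- universe[1:200]
  ps <- list(B1 = fake_program_set(list(shared), universe),
             B2 = fake_program_set(list(shared), universe),
             B3 = fake_program_set(list(shared), universe))
  cl <- match_programs(ps, consensus_config(top_n = 200))
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$batches_covered, c("B1", "B2", "B3"))
  expect_length(cl[[1]]$gene_set$genes, 200L)
})

test_that("pairwise-disjoint programs retain no cluster", {
  universe <- sprintf("g%03d", 1:90)
  ps <- list(B1 = fake_program_set(list(universe[1:30]), universe),
             B2 = fake_program_set(list(universe[31:60]), universe),
             B3 = fake_program_set(list(universe[61:90]), universe))
  expect_warning(cl <- match_programs(ps, consensus_config(top_n = 30)),
                 "no program cluster")
  expect_length(cl, 0L)
})

test_that("matching is invariant to batch order", {
  withr::local_seed(2)
  universe <- sprintf("g%03d", 1:200)
  shared <- sample(universe, 60)
  mk <- function() list(shared, sample(setdiff(universe, shared), 40))
  ps <- list(B1 = fake_program_set(mk(), universe),
             B2 = fake_program_set(mk(), universe),
             B3 = fake_program_set(mk(), universe))
  cl_a <- match_programs(ps, consensus_config(top_n = 60))
  cl_b <- match_programs(rev(ps), consensus_config(top_n = 60))
  genes_a <- lapply(cl_a, function(x) sort(x$gene_set$genes))
  genes_b <- lapply(cl_b, function(x) sort(x$gene_set$genes))
  expect_setequal(vapply(genes_a, paste, "", collapse = ","),
                  vapply(genes_b, paste, "", collapse = ","))
})

test_that("a planted shared module is matched and recovered across batches", {
  withr::local_seed(3)
  universe <- sprintf("g%03d", 1:400)
  truth <- universe[1:50]
  core <- truth[1:40]                      # 80% shared across batches
  ps <- lapply(1:3, function(b) {
    own <- setdiff(truth, core)[]
    realization <- c(core, sample(setdiff(universe, truth), 10))
    unique_prog <- sample(setdiff(universe, realization), 50)
    fake_program_set(list(sample(realization), unique_prog), universe)
  })
  names(ps) <- paste0("B", 1:3)
  cl <- match_programs(ps, consensus_config(top_n = 50))
  js <- vapply(cl, function(x) jaccard(x$gene_set, core), 0)
  expect_gte(max(js), 0.8)
})

test_that("refine_gene_set: identical and nested lists behave exactly", {
  universe <- sprintf("g%03d", 1:300)
  shared <- universe[1:250]
  ps <- list(B1 = fake_program_set(list(shared), universe),
             B2 = fake_program_set(list(shared), universe))
  cl <- match_programs(ps, consensus_config(top_n = 100))
  ref <- refine_gene_set(ps, cl[[1]],
                         consensus_config(top_n = 100,
                                          n_grid = c(50, 100, 150, 200)))
  expect_equal(ref$scree$n_intersection[ref$scree$n_input <= 250],
               ref$scree$n_input[ref$scree$n_input <= 250])

  # nested: batch2's ranked list is a prefix of batch1's
  ps2 <- list(B1 = fake_program_set(list(universe[1:200]), universe),
              B2 = fake_program_set(list(universe[1:120]), universe))
  cl2 <- match_programs(ps2, consensus_config(top_n = 120, cut_height = 0.9))
  ref2 <- refine_gene_set(ps2, cl2[[1]],
                          consensus_config(top_n = 120, n_grid = c(120)))
  expect_setequal(ref2$gene_set$genes, universe[1:120])  # = the smaller list
  # intersection size never decreases with N for nested lists
  ref3 <- refine_gene_set(ps2, cl2[[1]],
                          consensus_config(top_n = 100,
                                           n_grid = c(25, 50, 100, 120)))
  expect_true(all(diff(ref3$scree$n_intersection) >= 0))
})

test_that("independent random top-N lists intersect at the closed-form rate", {
  withr::local_seed(4)
  universe <- sprintf("g%04d", 1:2000)
  sizes <- replicate(40, {
    lists <- replicate(3, sample(universe, 200), simplify = FALSE)
    length(Reduce(intersect, lists))
  })
  # E|I| = 2000 * (200/2000)^3 = 2; Poisson-style bounds on the mean of 40
  expect_gt(mean(sizes), 2 - 3 * sqrt(2 / 40))
  expect_lt(mean(sizes), 2 + 3 * sqrt(2 / 40))
})
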