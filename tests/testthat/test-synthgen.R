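small_cfg <- function(seed = 1, ...) {
  cohort_config(n_genes = 200, n_celltypes = 2, n_identity_genes = 10,
                n_module_genes = 12, n_cells_per_type_per_donor = 15,
                seed = seed, ...)
}

test_that("cohort shape bookkeeping matches the design table", {
  cfg <- small_cfg()
  co <- generate_cohort(cfg)
  n_expected <- cfg$n_batches * length(cfg$conditions) *
    cfg$n_donors_per_condition * length(cfg$timepoints) *
    cfg$n_celltypes * cfg$n_cells_per_type_per_donor
  expect_identical(ncol(co$counts$values), n_expected)
  expect_identical(nrow(co$counts$values), cfg$n_genes)
  expect_identical(nrow(co$counts$cell_meta), n_expected)
  expect_setequal(unique(co$counts$cell_meta$batch), c("B1", "B2", "B3"))
})

test_that("identical config and seed give bit-identical cohorts", {
  a <- generate_cohort(small_cfg(seed = 5))
  b <- generate_cohort(small_cfg(seed = 5))
  expect_identical(as.matrix(a$counts$values), as.matrix(b$counts$values))
  expect_identical(a$truth$activity, b$truth$activity)
  c2 <- generate_cohort(small_cfg(seed = 6))
  expect_false(identical(as.matrix(a$counts$values), as.matrix(c2$counts$values)))
})

test_that("truth channel respects the configured condition x time ordering", {
  cfg <- cohort_config(n_genes = 300, n_celltypes = 3, n_identity_genes = 10,
                       n_module_genes = 20, n_cells_per_type_per_donor = 40,
                       trend_effect = c(1.0, 0.6, 0.6), seed = 2)
  co <- generate_cohort(cfg)
  meta <- co$counts$cell_meta
  act <- co$truth$activity
  m_rej <- tapply(act[meta$condition == "rejection"],
                  meta$timepoint[meta$condition == "rejection"], mean)
  m_sta <- tapply(act[meta$condition == "stable"],
                  meta$timepoint[meta$condition == "stable"], mean)
  expect_lt(m_rej[["T1"]], m_rej[["T0"]])
  expect_lt(abs(m_sta[["T1"]] - m_sta[["T0"]]) / m_sta[["T0"]], 0.15)
})

test_that("truth gene sets live inside the gene universe and counts are integer", {
  co <- generate_cohort(small_cfg(seed = 3))
  universe <- co$counts$gene_ids
  expect_true(all(co$truth$module_genes %in% universe))
  expect_true(all(unlist(co$truth$batch_module_genes) %in% universe))
  expect_true(all(unlist(co$truth$identity_genes) %in% universe))
  v <- co$counts$values@x
  expect_true(all(v >= 0) && all(v == round(v)))
  # batch realizations share the configured core fraction
  core <- Reduce(intersect, co$truth$batch_module_genes)
  expect_setequal(core, co$truth$module_genes)
  expect_equal(length(core), round(0.8 * 12))
})

test_that("cohort config invariants are validated with field names", {
  expect_error(small_cfg(n_module_genes = 300), "n_module_genes")
  expect_error(small_cfg(trend_effect = c(1, 1)), "trend_effect")
  expect_error(small_cfg(n_genes = 30), "n_genes")
  expect_error(cohort_config(n_batches = 0), "n_batches")
})

test_that("bulk generator: null shift keeps groups equal, planted shift separates", {
  b0 <- generate_bulk(bulk_config(n_samples_per_group = 40, module_shift = 0,
                                  seed = 4, n_genes = 300, n_module_genes = 20))
  sc0 <- bulk_module_score(b0$expr, b0$truth$module_genes)
  g <- b0$phenotype$group
  expect_lt(abs(mean(sc0[g == "stable"]) - mean(sc0[g == "rejection"])), 0.25)

  b1 <- generate_bulk(bulk_config(n_samples_per_group = 50, module_shift = 1,
                                  seed = 4, n_genes = 300, n_module_genes = 20))
  sc1 <- bulk_module_score(b1$expr, b1$truth$module_genes)
  g1 <- b1$phenotype$group
  ks <- ks_compare(sc1[g1 == "stable"], sc1[g1 == "rejection"])
  expect_lt(ks$p, 0.05)
})

test_that("bulk ligand gene tracks the latent module score", {
  b <- generate_bulk(bulk_config(n_samples_per_group = 50, noise_sigma = 0.3,
                                 seed = 8, n_genes = 300, n_module_genes = 20))
  r <- cor(b$expr[b$truth$ligand_gene, ], b$truth$module_score)
  expect_gt(r, 0.5)
})

test_that("annotation generator: null TF construction gives OR near 1", {
  genes <- sprintf("G%05d", 1:2000)
  mod <- sample(genes, 61)
  ors <- vapply(1:20, function(i) {
    ann <- generate_annotations(genes, tf_fraction = 0.1, seed = i)
    fisher_enrichment(mod, ann$tf_genes, genes)$OR
  }, 0)
  expect_lt(abs(mean(ors) - 1), 0.3)
})

test_that("annotation generator realizes a planted odds ratio", {
  genes <- sprintf("G%05d", 1:2000)
  mod <- genes[1:61]
  ors <- vapply(1:10, function(i) {
    ann <- generate_annotations(genes, tf_fraction = 0.1, seed = 100 + i,
                                module_genes = mod, tf_or = 5)
    fisher_enrichment(mod, ann$tf_genes, genes)$OR
  }, 0)
  expect_gt(mean(ors >= 3 & ors <= 8), 0.7)
})

test_that("annotation generator bookkeeping and infeasibility errors", {
  genes <- sprintf("G%05d", 1:500)
  ann <- generate_annotations(genes, n_lr_pairs = 20, seed = 2)
  expect_identical(nrow(ann$lr), 20L)
  expect_true(all(ann$lr$category %in% c("cytokine", "other")))
  expect_false(any(duplicated(c(ann$lr$ligand, ann$lr$receptor))))
  expect_error(generate_annotations(genes, tf_or = 5, seed = 1),
               "module_genes")
  expect_error(
    generate_annotations(genes, tf_fraction = 0.001, tf_or = 2,
                         module_genes = genes[1:5], seed = 1),
    "infeasible")
})

test_that("cohort and bulk writers round-trip through the readers", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_cfg(seed = 9))
  write_cohort(co, file.path(dir, "cohort"))
  back <- suppressMessages(read_count_matrix(file.path(dir, "cohort"),
                                             format = "mtx"))
  expect_equal(as.matrix(back$values), as.matrix(co$counts$values))
  expect_identical(back$cell_meta$cell_type, co$counts$cell_meta$cell_type)
  truth <- jsonlite::read_json(file.path(dir, "cohort", "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$module_genes, co$truth$module_genes)
})
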