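#' Configuration for the synthetic bulk-tissue generator
#'
#' Two-group (stable vs rejection) bulk expression on the log scale.
#' Each sample carries a latent module score; module genes are shifted by
#' that score, which itself is shifted by `module_shift` in the rejection
#' group; one designated ligand gene tracks the latent score linearly with
#' positive slope (the chemokine-ligand analog whose tissue expression rises
#' with module-high infiltration).
#'
#' @param n_samples_per_group samples per group (>= 4; quartile
#'   stratification needs at least 4 samples).
#' @param groups two group labels; the second receives `module_shift`.
#' @param n_genes gene universe size.
#' @param n_module_genes module size (ignored when `module_genes` given).
#' @param module_genes optional explicit module gene ids.
#' @param module_shift mean shift (log-scale units) of the latent module
#'   score in the rejection group.
#' @param ligand_gene gene id whose expression tracks the module score;
#'   defaults to the first non-module gene.
#' @param ligand_beta slope of ligand on latent score (> 0).
#' @param score_sigma SD of the latent per-sample module score.
#' @param noise_sigma residual SD of gene expression.
#' @param seed mandatory integer seed.
#' @return a `bulk_config` list.
#' @export
bulk_config <- function(n_samples_per_group = 50L,
                        groups = c("stable", "rejection"),
                        n_genes = 2000L, n_module_genes = 61L,
                        module_genes = NULL,
                        module_shift = 1, ligand_gene = NULL,
                        ligand_beta = 1, score_sigma = 0.5,
                        noise_sigma = 0.3, seed = 1L) {
  cfg <- list(
    n_samples_per_group = check_count(n_samples_per_group, "n_samples_per_group", min = 4L),
    groups = as.character(groups),
    n_genes = check_count(n_genes, "n_genes"),
    n_module_genes = check_count(n_module_genes, "n_module_genes"),
    module_genes = if (is.null(module_genes)) NULL else as.character(module_genes),
    module_shift = as.numeric(module_shift),
    ligand_gene = if (is.null(ligand_gene)) NULL else as.character(ligand_gene),
    ligand_beta = as.numeric(ligand_beta),
    score_sigma = check_fraction(score_sigma, "score_sigma", 0, Inf),
    noise_sigma = check_fraction(noise_sigma, "noise_sigma", 0, Inf),
    seed = check_count(seed, "seed", min = 0L))
  if (length(cfg$groups) != 2L) stop_invalid("groups", "exactly two groups")
  if (cfg$ligand_beta <= 0) stop_invalid("ligand_beta", "must be positive")
  structure(cfg, class = "bulk_config")
}

#' Generate a synthetic bulk expression matrix with phenotypes
#'
#' @param config a [bulk_config()].
#' @return a `synthetic_bulk`: list with `expr` (genes x samples matrix,
#'   log-scale), `phenotype` (data.frame sample_id, group) and `truth`
#'   (module genes, per-sample latent score, ligand gene).
#' @export
generate_bulk <- function(config) {
  stopifnot(inherits(config, "bulk_config"))
  cfg <- config
  with_seed(cfg$seed, {
    gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    module_genes <- cfg$module_genes %||% sample(gene_ids, cfg$n_module_genes)
    if (!all(module_genes %in% gene_ids)) {
      stop_invalid("module_genes", "not all inside the gene universe")
    }
    ligand <- cfg$ligand_gene %||% setdiff(gene_ids, module_genes)[1L]
    n <- 2L * cfg$n_samples_per_group
    group <- rep(cfg$groups, each = cfg$n_samples_per_group)
    sample_ids <- sprintf("S%03d", seq_len(n))
    score <- cfg$module_shift * (group == cfg$groups[2L]) +
      rnorm(n, 0, cfg$score_sigma)
    baseline <- rnorm(cfg$n_genes, mean = 6, sd = 1.5)
    names(baseline) <- gene_ids
    expr <- matrix(baseline, nrow = cfg$n_genes, ncol = n,
                   dimnames = list(gene_ids, sample_ids))
    expr[module_genes, ] <- expr[module_genes, ] +
      rep(score, each = length(module_genes))
    expr[ligand, ] <- baseline[ligand] + cfg$ligand_beta * score
    expr <- expr + matrix(rnorm(length(expr), 0, cfg$noise_sigma), nrow = nrow(expr))
    phenotype <- data.frame(sample_id = sample_ids, group = group,
                            stringsAsFactors = FALSE)
    structure(list(expr = expr, phenotype = phenotype,
                   truth = list(module_genes = module_genes,
                                module_score = setNames(score, sample_ids),
                                ligand_gene = ligand, config = cfg)),
              class = "synthetic_bulk")
  })
}

#' Write a synthetic bulk dataset to disk
#'
#' Expression as a genes x samples TSV, phenotypes as `phenotype.tsv`,
#' truth as JSON.
#'
#' @param bulk a `synthetic_bulk`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bulk <- function(bulk, dir) {
  stopifnot(inherits(bulk, "synthetic_bulk"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(gene_id = rownames(bulk$expr), bulk$expr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, file.path(dir, "bulk.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bulk$phenotype, file.path(dir, "phenotype.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- bulk$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate synthetic annotation tables
#'
#' Produces the three annotation inputs the enrichment and interaction
#' statistics consume: a transcription-factor gene list, a gene-disease
#' association (GDA) table, and a ligand-receptor interaction table with a
#' `cytokine` category. Optionally plants TF and/or GDA enrichment of a
#' given module at a requested odds ratio by raising the within-module
#' membership probability.
#'
#' @param genes gene universe (character vector) or a single integer count.
#' @param tf_fraction background fraction of TF genes, in (0,1).
#' @param gda_fraction background fraction of genes with >= 1 disease
#'   association, in (0,1).
#' @param n_lr_pairs number of ligand-receptor rows.
#' @param seed mandatory integer seed.
#' @param module_genes optional module to enrich.
#' @param tf_or,gda_or planted odds ratios (1 = no enrichment).
#' @param cytokine_fraction fraction of LR pairs in the `cytokine` category.
#' @param disease_terms pool of disease-term labels for the GDA table.
#' @return list with `tf_genes` (character), `gda` (data.frame gene,
#'   disease), `lr` (data.frame ligand, receptor, category).
#' @export
generate_annotations <- function(genes, tf_fraction = 0.1, gda_fraction = 0.2,
                                 n_lr_pairs = 20L, seed = 1L,
                                 module_genes = NULL, tf_or = 1, gda_or = 1,
                                 cytokine_fraction = 0.5,
                                 disease_terms = c("juvenile arthritis",
                                                   "lymphoma", "polyarthritis",
                                                   "lupus", "vasculitis",
                                                   "nephritis")) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("G%05d", seq_len(check_count(genes, "genes")))
  }
  genes <- as.character(genes)
  check_fraction(tf_fraction, "tf_fraction", 0, 1, open_hi = TRUE)
  check_fraction(gda_fraction, "gda_fraction", 0, 1, open_hi = TRUE)
  n_lr_pairs <- check_count(n_lr_pairs, "n_lr_pairs")
  if ((tf_or != 1 || gda_or != 1) && is.null(module_genes)) {
    stop_invalid("module_genes", "required when planting tf_or or gda_or != 1")
  }
  module_genes <- if (is.null(module_genes)) character() else as_genes(module_genes)
  if (!all(module_genes %in% genes)) {
    stop_invalid("module_genes", "not all inside the gene universe")
  }
  if (2L * n_lr_pairs > length(genes)) {
    stop_invalid("n_lr_pairs", "gene universe too small for disjoint pairs")
  }
  # odds-ratio-matched membership probability inside the module
  plant_prob <- function(p0, or, field) {
    p1 <- or * p0 / (1 - p0 + or * p0)
    n_mod <- length(module_genes)
    if (or != 1 && n_mod * p1 < 1) {
      stop_invalid(field, sprintf(
        "requested enrichment infeasible: expected module hits %.2f < 1", n_mod * p1))
    }
    p1
  }
  tf_p1 <- plant_prob(tf_fraction, tf_or, "tf_or")
  gda_p1 <- plant_prob(gda_fraction, gda_or, "gda_or")

  with_seed(seed, {
    in_mod <- genes %in% module_genes
    p_tf <- ifelse(in_mod, tf_p1, tf_fraction)
    tf_genes <- genes[runif(length(genes)) < p_tf]
    p_gda <- ifelse(in_mod, gda_p1, gda_fraction)
    gda_genes <- genes[runif(length(genes)) < p_gda]
    gda <- if (length(gda_genes)) {
      n_terms <- sample(1:3, length(gda_genes), replace = TRUE)
      data.frame(
        gene = rep(gda_genes, n_terms),
        disease = unlist(lapply(n_terms, function(k) sample(disease_terms, k))),
        stringsAsFactors = FALSE)
    } else data.frame(gene = character(), disease = character())
    lr_genes <- sample(genes, 2L * n_lr_pairs)
    lr <- data.frame(
      ligand = lr_genes[seq_len(n_lr_pairs)],
      receptor = lr_genes[n_lr_pairs + seq_len(n_lr_pairs)],
      category = ifelse(runif(n_lr_pairs) < cytokine_fraction, "cytokine", "other"),
      stringsAsFactors = FALSE)
    list(tf_genes = tf_genes, gda = gda, lr = lr)
  })
}
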