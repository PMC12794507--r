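#' Run the end-to-end module-discovery pipeline from one configuration
#'
#' Orchestrates simulate -> discover -> consensus -> score -> validate ->
#' enrich -> interact -> classify. Stages communicate only via on-disk
#' artifacts under `output_dir`, so individual stages can be re-run (pass
#' `stages`) against a previous run's outputs. Every run writes a
#' `provenance.json` with the config, its checksum and the seed; a failing
#' stage leaves a `FAILED` marker naming the stage and re-raises the error.
#'
#' Configuration (YAML file or list): top-level `seed` (mandatory) and
#' `output_dir`, exactly one of `synthgen:` (blocks `cohort`, optional
#' `bulk`, `annotations`, passed to the generator constructors) or
#' `input:` (paths `counts`/`format`, optional `bulk`, `phenotype`), plus
#' optional per-stage blocks `discovery` (fields of [discovery_config()],
#' or `k` for a fixed program count), `consensus` ([consensus_config()]
#' fields), `scoring` (`rmax`), `cohortstats` (`n_random`, `n_cells`,
#' `n_perm`), `interactions` ([lr_config()] fields) and `classify`
#' ([cv_plan()] fields).
#'
#' @param config path to a YAML file or an equivalent nested list.
#' @param stages subset of stages to run (default: all that are
#'   configured).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_invalid("seed", "mandatory in the pipeline config")
  seed <- check_count(config$seed, "seed", min = 0L)
  outdir <- config$output_dir %||% "scmodules_run"
  has_synth <- !is.null(config$synthgen)
  has_input <- !is.null(config$input)
  if (has_synth == has_input) {
    stop_invalid("synthgen/input", "exactly one input source must be configured")
  }
  all_stages <- c("simulate", "discover", "consensus", "score", "validate",
                  "enrich", "interact", "classify")
  stages <- stages %||% all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (has_input) stages <- setdiff(stages, "simulate")
  if (is.null(config$synthgen$annotations)) stages <- setdiff(stages, c("enrich", "interact"))
  if (is.null(config$synthgen$bulk) && is.null(config$input$bulk)) {
    stages <- setdiff(stages, c("interact", "classify"))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(cfg_file)), seed = seed,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("scmodules")),
         stages = stages),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE)
  state <- new.env(parent = emptyenv())
  for (stage in all_stages[all_stages %in% stages]) {
    fn <- get(paste0("stage_", stage), mode = "function")
    ok <- tryCatch({
      fn(config, seed, outdir, state)
      TRUE
    }, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    if (ok) message(sprintf("stage %s: done", stage))
  }
  invisible(outdir)
}

# ---- stage helpers: each loads its inputs from `state` or from disk ----

pipeline_counts <- function(config, outdir, state) {
  if (!is.null(state$cohort)) return(state$cohort$counts)
  if (!is.null(config$input$counts)) {
    return(read_count_matrix(config$input$counts,
                             format = config$input$format %||% "mtx",
                             meta_path = config$input$metadata))
  }
  read_count_matrix(file.path(outdir, "simulate", "cohort"), format = "mtx")
}

pipeline_bulk <- function(config, outdir, state) {
  if (!is.null(state$bulk)) return(state$bulk)
  if (!is.null(config$input$bulk)) {
    expr_cm <- read_count_matrix(config$input$bulk, format = "tsv")
    pheno <- read.delim(config$input$phenotype, stringsAsFactors = FALSE)
    return(list(expr = as.matrix(expr_cm$values), phenotype = pheno,
                truth = NULL))
  }
  dir <- file.path(outdir, "simulate", "bulk")
  if (!dir.exists(dir)) return(NULL)
  expr_cm <- suppressWarnings(read_count_matrix(file.path(dir, "bulk.tsv"),
                                                format = "tsv"))
  pheno <- read.delim(file.path(dir, "phenotype.tsv"), stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(expr = as.matrix(expr_cm$values), phenotype = pheno, truth = truth)
}

pipeline_module <- function(outdir, state) {
  if (!is.null(state$module)) return(state$module)
  sets <- read_gene_sets(file.path(outdir, "consensus", "modules.gmt"))
  sets[[1L]]
}

stage_simulate <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "simulate")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc_args <- config$synthgen$cohort %||% list()
  cc_args$seed <- cc_args$seed %||% seed
  cohort <- generate_cohort(do.call(cohort_config, cc_args))
  write_cohort(cohort, file.path(dir, "cohort"))
  state$cohort <- cohort
  if (!is.null(config$synthgen$bulk)) {
    b_args <- config$synthgen$bulk
    b_args$seed <- b_args$seed %||% (seed + 1L)
    b_args$module_genes <- b_args$module_genes %||% cohort$truth$module_genes
    b_args$n_genes <- b_args$n_genes %||% cohort$truth$config$n_genes
    bulk <- generate_bulk(do.call(bulk_config, b_args))
    write_bulk(bulk, file.path(dir, "bulk"))
    state$bulk <- bulk
  }
  if (!is.null(config$synthgen$annotations)) {
    a_args <- config$synthgen$annotations
    a_args$genes <- cohort$counts$gene_ids
    a_args$seed <- a_args$seed %||% (seed + 2L)
    if (!is.null(a_args$tf_or) || !is.null(a_args$gda_or)) {
      a_args$module_genes <- a_args$module_genes %||% cohort$truth$module_genes
    }
    ann <- do.call(generate_annotations, a_args)
    writeLines(ann$tf_genes, file.path(dir, "tf_genes.txt"))
    write.table(ann$gda, file.path(dir, "gda.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ann$lr, file.path(dir, "lr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$annotations <- ann
  }
  invisible(NULL)
}

stage_discover <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "discover")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- pipeline_counts(config, outdir, state)
  dcfg_args <- config$discovery %||% list()
  fixed_k <- dcfg_args$k
  dcfg_args$k <- NULL
  dcfg_args$seed <- dcfg_args$seed %||% seed
  dcfg <- do.call(discovery_config, dcfg_args)
  batches <- sort(unique(counts$cell_meta$batch))
  program_sets <- list()
  for (b in batches) {
    sub <- subset_counts(counts, cells = counts$cell_meta$batch == b)
    sel <- select_overdispersed(sub, n_top = min(dcfg$n_top_genes,
                                                 nrow(sub$values)))
    subg <- subset_counts(sub, genes = sel$genes$genes)
    ps <- if (!is.null(fixed_k)) {
      consensus_nmf(subg, K = fixed_k, config = dcfg)
    } else {
      select_k(subg, config = dcfg)$programs
    }
    program_sets[[b]] <- ps
    write.table(data.frame(program = rownames(ps$spectra), ps$spectra,
                           check.names = FALSE),
                file.path(dir, sprintf("spectra_%s.tsv", b)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(cell_id = rownames(ps$usages), ps$usages,
                           check.names = FALSE),
                file.path(dir, sprintf("usages_%s.tsv", b)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(batch = b, K = ps$K, stability = ps$stability,
                              error = ps$error),
                         file.path(dir, sprintf("metrics_%s.json", b)),
                         auto_unbox = TRUE, digits = NA)
  }
  state$program_sets <- program_sets
  invisible(NULL)
}

stage_consensus <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "consensus")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  program_sets <- state$program_sets
  if (is.null(program_sets)) {
    stop("consensus stage needs the discover stage's programs in this run",
         call. = FALSE)
  }
  ccfg <- do.call(consensus_config, config$consensus %||% list())
  clusters <- match_programs(program_sets, ccfg)
  if (!length(clusters)) stop("no cross-batch consensus cluster retained",
                              call. = FALSE)
  sets <- Filter(Negate(is.null), lapply(clusters, `[[`, "gene_set"))
  for (i in seq_along(sets)) sets[[i]]$name <- sprintf("module_%d", i)
  write_gene_sets(sets, file.path(dir, "modules.gmt"))
  jsonlite::write_json(
    lapply(clusters, function(cl) list(
      members = cl$members, batches = cl$batches_covered,
      n_genes = if (is.null(cl$gene_set)) 0L else length(cl$gene_set$genes),
      scree = cl$scree)),
    file.path(dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  state$clusters <- clusters
  state$module <- sets[[1L]]
  invisible(NULL)
}

stage_score <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "score")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- pipeline_counts(config, outdir, state)
  module <- pipeline_module(outdir, state)
  rmax <- config$scoring$rmax %||% 1500L
  scores <- ucell_score(counts, module, rmax = min(rmax, nrow(counts$values)))
  write_scores(scores, file.path(dir, "cell_scores.tsv"), counts$cell_meta)
  state$scores <- scores
  bulk <- pipeline_bulk(config, outdir, state)
  if (!is.null(bulk)) {
    bscores <- bulk_module_score(bulk$expr, module)
    write_scores(bscores, file.path(dir, "bulk_scores.tsv"), bulk$phenotype)
    state$bulk_scores <- bscores
  }
  invisible(NULL)
}

stage_validate <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "validate")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- pipeline_counts(config, outdir, state)
  module <- pipeline_module(outdir, state)
  scores <- state$scores %||% stop("validate stage needs the score stage",
                                   call. = FALSE)
  cs <- config$cohortstats %||% list()
  corr <- correlation_null_test(counts, module,
                                n_random = cs$n_random %||% 1000L,
                                seed = seed + 10L)
  jsonlite::write_json(list(observed = as.list(corr$observed),
                            p = as.list(corr$p)),
                       file.path(dir, "correlation_null.json"),
                       auto_unbox = TRUE, digits = NA)
  trends <- trend_regression(scores, counts$cell_meta)
  write.table(trends, file.path(dir, "trends.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  conds <- sort(unique(counts$cell_meta$condition))
  if (length(conds) == 2L) {
    sa <- scores[counts$cell_meta$condition == conds[1L]]
    sb <- scores[counts$cell_meta$condition == conds[2L]]
    n_cells <- min(cs$n_cells %||% 200L, length(sa), length(sb))
    perm <- permutation_robustness(sa, sb, n_cells = n_cells,
                                   n_perm = cs$n_perm %||% 5000L,
                                   seed = seed + 11L)
    ks <- ks_compare(sa, sb)
    jsonlite::write_json(
      list(proportion_significant = perm$proportion_significant,
           n_cells = perm$n_cells, n_perm = perm$n_perm,
           ks_D = ks$D, ks_p = ks$p, seed = perm$seed),
      file.path(dir, "robustness.json"), auto_unbox = TRUE, digits = NA)
  }
  bulk <- pipeline_bulk(config, outdir, state)
  if (!is.null(bulk) && !is.null(state$bulk_scores) &&
      !is.null(bulk$truth$ligand_gene)) {
    strat <- stratify_by_module(state$bulk_scores,
                                setNames(bulk$expr[bulk$truth$ligand_gene, ],
                                         colnames(bulk$expr)))
    write.table(strat$comparisons, file.path(dir, "stratification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

stage_enrich <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "enrich")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- pipeline_counts(config, outdir, state)
  module <- pipeline_module(outdir, state)
  ann <- state$annotations %||% list(
    tf_genes = readLines(file.path(outdir, "simulate", "tf_genes.txt")),
    gda = read.delim(file.path(outdir, "simulate", "gda.tsv"),
                     stringsAsFactors = FALSE))
  background <- gene_set(union(counts$gene_ids, module$genes), name = "universe")
  fe <- fisher_enrichment(module, gene_set(ann$tf_genes, "TF"), background)
  gda <- gda_permutation(module, ann$gda, background, seed = seed + 12L)
  terms <- split(ann$gda$gene, ann$gda$disease)
  ora_tab <- ora(module, terms, background)
  write.table(ora_tab, file.path(dir, "ora.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tf_or = fe$OR, tf_p = fe$p, tf_table = as.vector(fe$table),
         gda_observed_fraction = gda$observed_fraction, gda_p = gda$p),
    file.path(dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_interact <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "interact")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- pipeline_counts(config, outdir, state)
  bulk <- pipeline_bulk(config, outdir, state)
  ann <- state$annotations %||% list(
    lr = read.delim(file.path(outdir, "simulate", "lr.tsv"),
                    stringsAsFactors = FALSE))
  lcfg <- do.call(lr_config, config$interactions %||% list())
  pairs <- pair_ligand_receptor(bulk$expr, bulk$phenotype$group, counts,
                                ann$lr, lcfg)
  write.table(pairs, file.path(dir, "lr_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

stage_classify <- function(config, seed, outdir, state) {
  dir <- file.path(outdir, "classify")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  module <- pipeline_module(outdir, state)
  bulk <- pipeline_bulk(config, outdir, state)
  cl_args <- config$classify %||% list()
  cl_args$seed <- cl_args$seed %||% (seed + 13L)
  plan <- do.call(cv_plan, cl_args)
  report <- compare_feature_sets(bulk$expr, bulk$phenotype$group, module, plan)
  write.table(report, file.path(dir, "classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
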