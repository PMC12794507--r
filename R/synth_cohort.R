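#' Configuration for the synthetic single-cell cohort generator
#'
#' Defines a multi-batch longitudinal PBMC-like cohort: per batch, donors of
#' each condition are sampled at ordered timepoints, and each donor
#' contributes cells of every cell type. Counts are negative-binomial
#' (gamma-Poisson) with log-normal per-cell library sizes. Each cell type
#' carries an identity program (a disjoint gene set with elevated means in
#' that type); on top sits a single activity module expressed across all
#' cell types, whose per-cell intensity is a continuous log-normal latent
#' scaled by condition x timepoint. Batch effects are multiplicative
#' gene-wise log-normal offsets, because downstream discovery analyses
#' batches independently.
#'
#' Cross-batch module overlap: each batch expresses an `n_module_genes`
#' realization of the activity module consisting of a shared core
#' (`module_batch_overlap` of the genes — the ground-truth module, since
#' only the shared part constitutes a cross-batch module) plus
#' batch-specific genes. The ideal cross-batch intersection recovers the
#' core exactly.
#'
#' @param n_batches number of experimental batches (default 3).
#' @param n_celltypes number of cell types (default 5).
#' @param n_donors_per_condition donors per condition within each batch.
#' @param n_cells_per_type_per_donor cells per (donor, timepoint, cell type).
#' @param n_genes gene universe size (default 2000).
#' @param n_module_genes size of each batch's activity-module realization
#'   (default 61).
#' @param n_identity_genes identity-program genes per cell type.
#' @param timepoints ordered timepoint labels.
#' @param conditions condition labels; the last one (`"rejection"`) receives
#'   the `trend_effect`.
#' @param trend_effect per-timepoint multiplicative shift of module-gene
#'   activity in rejection donors (length = number of timepoints). The
#'   default declining profile mirrors an activity module that is depleted
#'   from circulation during rejection.
#' @param module_fc mean fold-elevation of module genes over baseline.
#' @param identity_fc fold-elevation of identity genes in their own type.
#' @param activity_sigma sdlog of the per-cell log-normal activity latent;
#'   0 switches the module off (all genes independent).
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param libsize_sigma sdlog of per-cell library-size factors.
#' @param batch_sigma sdlog of per-batch gene-wise offsets.
#' @param module_batch_overlap fraction of module genes shared by all
#'   batches (default 0.8).
#' @param baseline_meanlog,baseline_sdlog log-normal law of baseline gene
#'   means.
#' @param min_baseline_quantile planted (identity and module) genes draw
#'   their baseline from above this quantile of the baseline law
#'   (default 0.5): discovered modules consist of detectably expressed
#'   genes by construction, so the planted truth must too, or recovery
#'   tests would measure dropout rather than the pipeline.
#' @param seed mandatory integer seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_batches = 3L, n_celltypes = 5L,
                          n_donors_per_condition = 1L,
                          n_cells_per_type_per_donor = 50L,
                          n_genes = 2000L, n_module_genes = 61L,
                          n_identity_genes = 40L,
                          timepoints = c("T0", "T1", "T2"),
                          conditions = c("stable", "rejection"),
                          trend_effect = c(1.0, 0.6, 0.6),
                          module_fc = 3, identity_fc = 4,
                          activity_sigma = 0.5,
                          nb_dispersion = 0.4, libsize_sigma = 0.35,
                          batch_sigma = 0.15,
                          module_batch_overlap = 0.8,
                          baseline_meanlog = log(0.5), baseline_sdlog = 1,
                          min_baseline_quantile = 0.5,
                          seed = 1L) {
  cfg <- list(
    n_batches = check_count(n_batches, "n_batches"),
    n_celltypes = check_count(n_celltypes, "n_celltypes"),
    n_donors_per_condition = check_count(n_donors_per_condition, "n_donors_per_condition"),
    n_cells_per_type_per_donor = check_count(n_cells_per_type_per_donor, "n_cells_per_type_per_donor"),
    n_genes = check_count(n_genes, "n_genes"),
    n_module_genes = check_count(n_module_genes, "n_module_genes"),
    n_identity_genes = check_count(n_identity_genes, "n_identity_genes"),
    timepoints = as.character(timepoints),
    conditions = as.character(conditions),
    trend_effect = as.numeric(trend_effect),
    module_fc = as.numeric(module_fc),
    identity_fc = as.numeric(identity_fc),
    activity_sigma = check_fraction(activity_sigma, "activity_sigma", 0, Inf, open_lo = FALSE),
    nb_dispersion = check_fraction(nb_dispersion, "nb_dispersion", 0, Inf),
    libsize_sigma = check_fraction(libsize_sigma, "libsize_sigma", 0, Inf, open_lo = FALSE),
    batch_sigma = check_fraction(batch_sigma, "batch_sigma", 0, Inf, open_lo = FALSE),
    module_batch_overlap = check_fraction(module_batch_overlap, "module_batch_overlap"),
    baseline_meanlog = as.numeric(baseline_meanlog),
    baseline_sdlog = as.numeric(baseline_sdlog),
    min_baseline_quantile = check_fraction(min_baseline_quantile,
                                           "min_baseline_quantile",
                                           0, 1, open_lo = FALSE, open_hi = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_module_genes >= cfg$n_genes) {
    stop_invalid("n_module_genes", "must be smaller than n_genes")
  }
  if (length(cfg$trend_effect) != length(cfg$timepoints)) {
    stop_invalid("trend_effect", sprintf(
      "length %d does not match %d timepoints",
      length(cfg$trend_effect), length(cfg$timepoints)))
  }
  if (any(cfg$trend_effect <= 0)) stop_invalid("trend_effect", "must be positive")
  if (length(cfg$conditions) < 1L) stop_invalid("conditions", "at least one condition")
  n_core <- round(cfg$module_batch_overlap * cfg$n_module_genes)
  n_special <- cfg$n_celltypes * cfg$n_identity_genes + n_core +
    cfg$n_batches * (cfg$n_module_genes - n_core)
  if (n_special > cfg$n_genes) {
    stop_invalid("n_genes", sprintf(
      "too small: %d identity + module genes exceed %d genes", n_special, cfg$n_genes))
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic single-cell cohort with ground truth
#'
#' Draws a multi-batch negative-binomial count matrix following
#' [cohort_config()] and returns it together with a truth channel (planted
#' gene sets and per-cell latent activity) for parameter-recovery tests.
#' Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: list with `counts` (a [count_matrix()])
#'   and `truth` (list: `module_genes`, `batch_module_genes`,
#'   `identity_genes`, `activity` per-cell latent, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    # plant disjoint identity programs and the activity module: a shared
    # core (the ground-truth module) plus batch-specific extra genes
    n_core <- round(cfg$module_batch_overlap * cfg$n_module_genes)
    n_extra <- cfg$n_module_genes - n_core
    n_ident <- cfg$n_celltypes * cfg$n_identity_genes
    special <- sample(gene_ids, n_ident + n_core + cfg$n_batches * n_extra)
    celltypes <- sprintf("CT%d", seq_len(cfg$n_celltypes))
    identity_genes <- split(special[seq_len(n_ident)],
                            rep(celltypes, each = cfg$n_identity_genes))
    identity_genes <- identity_genes[celltypes]
    core <- special[n_ident + seq_len(n_core)]
    extra_pool <- special[(n_ident + n_core + 1L):length(special)]
    batch_ids <- sprintf("B%d", seq_len(cfg$n_batches))
    batch_module_genes <- lapply(seq_len(cfg$n_batches), function(b) {
      own <- if (n_extra) extra_pool[(b - 1L) * n_extra + seq_len(n_extra)] else character()
      c(core, own)
    })
    names(batch_module_genes) <- batch_ids
    module_genes <- core

    # cell design table
    design <- expand.grid(
      cell_type = celltypes,
      timepoint = cfg$timepoints,
      donor_idx = seq_len(cfg$n_donors_per_condition),
      condition = cfg$conditions,
      batch = batch_ids,
      stringsAsFactors = FALSE)
    design <- design[rep(seq_len(nrow(design)), each = cfg$n_cells_per_type_per_donor), ]
    rownames(design) <- NULL
    n_cells <- nrow(design)
    design$donor <- paste0(design$batch, "_", design$condition, "_D", design$donor_idx)
    design$cell_id <- sprintf("cell_%06d", seq_len(n_cells))

    # per-cell latent activity: condition x timepoint trend x log-normal spread
    tp_idx <- match(design$timepoint, cfg$timepoints)
    is_rej <- design$condition == cfg$conditions[length(cfg$conditions)] &
      length(cfg$conditions) > 1L
    trend_mult <- ifelse(is_rej, cfg$trend_effect[tp_idx], 1)
    activity <- trend_mult * rlnorm(n_cells, meanlog = 0, sdlog = cfg$activity_sigma)

    baseline <- rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
    names(baseline) <- gene_ids
    # planted genes: truncate the baseline law below, so the planted truth
    # sits among detectably expressed genes
    if (cfg$min_baseline_quantile > 0) {
      u <- runif(length(special), cfg$min_baseline_quantile, 1)
      baseline[special] <- stats::qlnorm(u, cfg$baseline_meanlog, cfg$baseline_sdlog)
    }
    batch_offset <- matrix(rlnorm(cfg$n_genes * cfg$n_batches, 0, cfg$batch_sigma),
                           nrow = cfg$n_genes,
                           dimnames = list(gene_ids, batch_ids))
    libsize <- rlnorm(n_cells, 0, cfg$libsize_sigma)

    mu <- matrix(baseline, nrow = cfg$n_genes, ncol = n_cells,
                 dimnames = list(gene_ids, design$cell_id))
    # identity elevation
    for (ct in celltypes) {
      cells_ct <- design$cell_type == ct
      mu[identity_genes[[ct]], cells_ct] <- mu[identity_genes[[ct]], cells_ct] * cfg$identity_fc
    }
    # activity module, batch-resolved membership
    for (b in batch_ids) {
      cells_b <- design$batch == b
      mg <- batch_module_genes[[b]]
      mu[mg, cells_b] <- mu[mg, cells_b] *
        (cfg$module_fc * rep(activity[cells_b], each = length(mg)))
    }
    # batch offsets and library size
    for (b in batch_ids) {
      cells_b <- design$batch == b
      mu[, cells_b] <- mu[, cells_b] * batch_offset[, b]
    }
    mu <- sweep(mu, 2L, libsize, `*`)

    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                     nrow = cfg$n_genes, dimnames = dimnames(mu))
    meta <- design[, c("cell_id", "batch", "donor", "timepoint", "condition", "cell_type")]
    cm <- count_matrix(counts, cell_meta = meta, warn_nonint = FALSE)
    truth <- list(
      module_genes = module_genes,
      batch_module_genes = batch_module_genes,
      identity_genes = identity_genes,
      activity = setNames(activity, design$cell_id),
      config = cfg)
    structure(list(counts = cm, truth = truth), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d cells, %d batches, module of %d genes\n",
              nrow(x$counts$values), ncol(x$counts$values),
              length(unique(x$counts$cell_meta$batch)),
              length(x$truth$module_genes)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Counts as Matrix Market plus `features.tsv`/`barcodes.tsv`/`metadata.tsv`
#' sidecars; truth channel as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(cohort$counts, dir, format = "mtx")
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
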