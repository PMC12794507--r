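#' Configuration for ligand-receptor pairing
#'
#' @param expr_fraction fraction of expressed genes retained per group by
#'   mean expression (default 0.5).
#' @param category_filter interaction-table category to keep
#'   (default `"cytokine"`).
#' @param top_pairs_per_celltype pairs reported per cell type (default 5).
#' @param p_threshold differential-expression threshold per side
#'   (default 0.05).
#' @param same_direction require ligand and receptor to move the same way
#'   (both up in the second group); set `FALSE` to relax.
#' @return an `lr_config` list.
#' @export
lr_config <- function(expr_fraction = 0.5, category_filter = "cytokine",
                      top_pairs_per_celltype = 5L, p_threshold = 0.05,
                      same_direction = TRUE) {
  structure(list(
    expr_fraction = check_fraction(expr_fraction, "expr_fraction"),
    category_filter = as.character(category_filter),
    top_pairs_per_celltype = check_count(top_pairs_per_celltype,
                                         "top_pairs_per_celltype"),
    p_threshold = check_fraction(p_threshold, "p_threshold"),
    same_direction = isTRUE(same_direction)),
    class = "lr_config")
}

#' Top expressed genes per group
#'
#' Per group (cell type or tissue), genes are ordered by mean expression;
#' zero-mean genes are excluded first, then the top
#' `ceiling(fraction * n_expressed)` are retained. Genes tied with the
#' cutoff value are all included, so a set may exceed the nominal size.
#'
#' @param mat genes x columns matrix (counts or expression).
#' @param groups factor/character per column; a single label treats all
#'   columns as one group.
#' @param expr_fraction retained fraction (default 0.5).
#' @return named list of [gene_set()] (empty character for an all-zero
#'   group, with a warning).
#' @export
filter_expressed <- function(mat, groups, expr_fraction = 0.5) {
  if (inherits(mat, "count_matrix")) mat <- mat$values
  check_fraction(expr_fraction, "expr_fraction")
  if (length(groups) == 1L) groups <- rep(groups, ncol(mat))
  stopifnot(length(groups) == ncol(mat))
  out <- list()
  for (g in sort(unique(as.character(groups)))) {
    sub <- mat[, groups == g, drop = FALSE]
    mu <- Matrix::rowSums(sub) / ncol(sub)
    expressed <- mu > 0
    if (!any(expressed)) {
      warning(sprintf("group '%s' has no expressed genes", g))
      out[[g]] <- character()
      next
    }
    mu <- mu[expressed]
    n_keep <- ceiling(expr_fraction * length(mu))
    cutoff <- sort(mu, decreasing = TRUE)[n_keep]
    keep <- names(mu)[mu >= cutoff]  # ties at the cutoff all included
    out[[g]] <- gene_set(keep[order(-mu[keep], keep)],
                         name = sprintf("expressed_%s", g))
  }
  out
}

# Rank-biserial effect (2W/(n1 n2) - 1, positive = second group higher)
# and two-sided Wilcoxon p for one gene between two groups.
wilcox_effect <- function(x_ref, x_alt) {
  n1 <- length(x_alt); n2 <- length(x_ref)
  wt <- suppressWarnings(wilcox.test(x_alt, x_ref, exact = FALSE))
  r <- 2 * unname(wt$statistic) / (n1 * n2) - 1
  list(effect = r, p = wt$p.value)
}

#' Pair differentially expressed tissue ligands with cell receptors
#'
#' Ligands must be among the top-expressed fraction of the bulk tissue AND
#' differ between phenotype groups (two-sided Wilcoxon over samples);
#' receptors must be top-expressed within a cell type AND differ between
#' condition groups (Wilcoxon over cells). Candidates are joined on the
#' interaction table restricted to the configured category, optionally
#' requiring both sides up in the second group, ranked per cell type by
#' the product of the absolute rank-biserial effects, and truncated to
#' `top_pairs_per_celltype`.
#'
#' @param bulk_expr genes x samples matrix (tissue).
#' @param bulk_groups character per sample, two groups.
#' @param sc_counts a [count_matrix()] with `cell_type` and `condition`
#'   metadata.
#' @param interaction_table data.frame with columns ligand, receptor,
#'   category.
#' @param config an [lr_config()].
#' @param alt_bulk the bulk phenotype treated as the rejection-like (alt)
#'   group for effect signs; defaults to `"rejection"` when present, else
#'   the last sorted level.
#' @param alt_sc the single-cell condition treated as the alt group;
#'   same default rule.
#' @return data.frame (cell_type, ligand, receptor, ligand_effect,
#'   ligand_p, receptor_effect, receptor_p, rank_score), at most
#'   `top_pairs_per_celltype` rows per cell type. Positive effects mean
#'   higher in the alt group.
#' @export
pair_ligand_receptor <- function(bulk_expr, bulk_groups, sc_counts,
                                 interaction_table, config = lr_config(),
                                 alt_bulk = NULL, alt_sc = NULL) {
  stopifnot(inherits(config, "lr_config"),
            inherits(sc_counts, "count_matrix"))
  need <- c("ligand", "receptor", "category")
  if (!all(need %in% names(interaction_table))) {
    stop("interaction table needs columns ligand, receptor, category",
         call. = FALSE)
  }
  itab <- interaction_table[interaction_table$category == config$category_filter, ,
                            drop = FALSE]
  if (!nrow(itab)) {
    stop(sprintf("category '%s' not in interaction table; available: %s",
                 config$category_filter,
                 paste(sort(unique(interaction_table$category)), collapse = ", ")),
         call. = FALSE)
  }
  bulk_groups <- as.character(bulk_groups)
  glv <- sort(unique(bulk_groups))
  if (length(glv) != 2L) stop("bulk phenotype must have two groups", call. = FALSE)
  pick_alt <- function(levels, alt, field) {
    if (is.null(alt)) {
      if ("rejection" %in% levels) "rejection" else levels[length(levels)]
    } else {
      if (!alt %in% levels) stop_invalid(field, "not a group level")
      alt
    }
  }
  alt_bulk <- pick_alt(glv, alt_bulk, "alt_bulk")
  ref_bulk <- setdiff(glv, alt_bulk)

  # tissue side: expression filter, then DE over samples
  lig_pool <- intersect(as_genes(filter_expressed(bulk_expr, "tissue",
                                                  config$expr_fraction)$tissue),
                        unique(itab$ligand))
  lig_stats <- do.call(rbind, lapply(lig_pool, function(g) {
    w <- wilcox_effect(bulk_expr[g, bulk_groups == ref_bulk],
                       bulk_expr[g, bulk_groups == alt_bulk])
    data.frame(ligand = g, ligand_effect = w$effect, ligand_p = w$p,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(lig_stats)) {
    keep <- lig_stats$ligand_p < config$p_threshold
    if (config$same_direction) keep <- keep & lig_stats$ligand_effect > 0
    lig_stats <- lig_stats[keep, , drop = FALSE]
  }
  if (is.null(lig_stats) || !nrow(lig_stats)) {
    return(empty_lr_table())
  }

  # cell side: per cell type expression filter + DE over cells
  meta <- sc_counts$cell_meta
  clv <- sort(unique(meta$condition))
  if (length(clv) != 2L) stop("single-cell data must have two conditions", call. = FALSE)
  alt_sc <- pick_alt(clv, alt_sc, "alt_sc")
  ref_sc <- setdiff(clv, alt_sc)
  expr_by_type <- filter_expressed(sc_counts$values, meta$cell_type,
                                   config$expr_fraction)
  sc_dense <- as.matrix(sc_counts$values)
  out <- list()
  for (ct in sort(unique(meta$cell_type))) {
    rec_pool <- intersect(as_genes(expr_by_type[[ct]]), unique(itab$receptor))
    cells_ref <- meta$cell_type == ct & meta$condition == ref_sc
    cells_alt <- meta$cell_type == ct & meta$condition == alt_sc
    if (!any(cells_ref) || !any(cells_alt)) next
    rec_stats <- do.call(rbind, lapply(rec_pool, function(g) {
      w <- wilcox_effect(sc_dense[g, cells_ref], sc_dense[g, cells_alt])
      data.frame(receptor = g, receptor_effect = w$effect, receptor_p = w$p,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rec_stats) || !nrow(rec_stats)) next
    keep <- rec_stats$receptor_p < config$p_threshold
    if (config$same_direction) keep <- keep & rec_stats$receptor_effect > 0
    rec_stats <- rec_stats[keep, , drop = FALSE]
    if (!nrow(rec_stats)) next
    pairs <- merge(merge(itab[, c("ligand", "receptor")], lig_stats,
                         by = "ligand"),
                   rec_stats, by = "receptor")
    if (!nrow(pairs)) next
    pairs$cell_type <- ct
    pairs$rank_score <- abs(pairs$ligand_effect) * abs(pairs$receptor_effect)
    pairs <- pairs[order(-pairs$rank_score, pairs$ligand, pairs$receptor), ,
                   drop = FALSE]
    out[[ct]] <- head(pairs, config$top_pairs_per_celltype)
  }
  if (!length(out)) return(empty_lr_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("cell_type", "ligand", "receptor", "ligand_effect", "ligand_p",
          "receptor_effect", "receptor_p", "rank_score")]
}

empty_lr_table <- function() {
  data.frame(cell_type = character(), ligand = character(),
             receptor = character(), ligand_effect = numeric(),
             ligand_p = numeric(), receptor_effect = numeric(),
             receptor_p = numeric(), rank_score = numeric(),
             stringsAsFactors = FALSE)
}
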