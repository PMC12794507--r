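#' Fisher exact enrichment of a category in a module
#'
#' Builds the 2x2 table (module-in-category, module-out, rest-in-category,
#' rest-out) over a background universe and reports the plain
#' cross-product odds ratio together with the exact hypergeometric
#' two-sided p-value (probability-ordering rule). When a zero cell occurs
#' the odds ratio uses a Haldane 0.5 correction and is flagged.
#'
#' @param module a [gene_set()] or character vector; must be contained in
#'   `background`.
#' @param category a [gene_set()] or character vector; intersected with
#'   the background.
#' @param background the gene universe.
#' @return an `enrichment_result` list: `OR`, `p`, `table` (2x2 counts),
#'   `haldane` (logical), `category` name.
#' @export
fisher_enrichment <- function(module, category, background) {
  mod <- unique(as_genes(module))
  bg <- unique(as_genes(background))
  cat_name <- if (inherits(category, "gene_set")) category$name else "category"
  category <- intersect(unique(as_genes(category)), bg)
  offenders <- setdiff(mod, bg)
  if (length(offenders)) {
    stop(sprintf("module genes outside the background: %s",
                 paste(offenders, collapse = ", ")), call. = FALSE)
  }
  a <- length(intersect(mod, category))
  b <- length(mod) - a
  c_ <- length(category) - a
  d <- length(bg) - length(mod) - c_
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(c("module", "rest"), c("in_category", "out")))
  haldane <- any(tab == 0L)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(OR = or, p = p, table = tab, haldane = haldane,
                 category = cat_name),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> '%s': OR = %.3g%s, p = %.3g\n",
              x$category, x$OR, if (x$haldane) " (Haldane-corrected)" else "",
              x$p))
  print(x$table)
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the module against each annotation
#' set, restricted to the background universe, with Benjamini-Hochberg
#' adjustment across terms. Annotation sets disjoint from the background
#' are skipped with a warning.
#'
#' @param module a [gene_set()] or character vector within `background`.
#' @param annotation_sets list of [gene_set()] objects (or named list of
#'   character vectors).
#' @param background the gene universe.
#' @param fdr_threshold significance threshold on the adjusted p
#'   (default 0.05).
#' @return data.frame (term, k = overlap, K = term size in background,
#'   n = module size, N = background size, p, fdr, significant).
#' @export
ora <- function(module, annotation_sets, background, fdr_threshold = 0.05) {
  mod <- unique(as_genes(module))
  bg <- unique(as_genes(background))
  offenders <- setdiff(mod, bg)
  if (length(offenders)) {
    stop(sprintf("module genes outside the background: %s",
                 paste(offenders, collapse = ", ")), call. = FALSE)
  }
  if (!length(annotation_sets)) stop("no annotation sets given", call. = FALSE)
  if (inherits(annotation_sets, "gene_set")) annotation_sets <- list(annotation_sets)
  term_names <- names(annotation_sets) %||% vapply(annotation_sets, function(s) {
    if (inherits(s, "gene_set")) s$name else "term"
  }, "")
  if (is.null(names(annotation_sets))) names(annotation_sets) <- term_names
  N <- length(bg)
  n <- length(mod)
  rows <- list()
  for (term in names(annotation_sets)) {
    genes <- intersect(unique(as_genes(annotation_sets[[term]])), bg)
    if (!length(genes)) {
      warning(sprintf("term '%s' is disjoint from the background; skipped", term))
      next
    }
    k <- length(intersect(mod, genes))
    K <- length(genes)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[term]] <- data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
                               stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("all annotation sets were disjoint from the background",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p, out$term), , drop = FALSE]
}

#' Gene-disease association permutation test
#'
#' The observed fraction of module genes with at least one entry in the
#' gene-disease association table is compared with the fractions of
#' `n_perm` equal-size random gene sets drawn from the universe; the
#' empirical p is the add-one estimator
#' `(1 + #{null >= observed}) / (n_perm + 1)` and can never be 0.
#'
#' @param module a [gene_set()] or character vector within `universe`.
#' @param gda_table data.frame with a `gene` column (one row per
#'   association).
#' @param universe the gene universe the random sets are drawn from.
#' @param n_perm number of random sets (default 1000).
#' @param seed integer seed.
#' @return a `gda_perm_result` list: `observed_fraction`, `null_fractions`,
#'   `p`, `n_associated`, `n_module`.
#' @export
gda_permutation <- function(module, gda_table, universe, n_perm = 1000L,
                            seed = 1L) {
  mod <- unique(as_genes(module))
  uni <- unique(as_genes(universe))
  if (!length(uni)) stop("empty universe", call. = FALSE)
  offenders <- setdiff(mod, uni)
  if (length(offenders)) {
    stop(sprintf("module genes outside the universe: %s",
                 paste(offenders, collapse = ", ")), call. = FALSE)
  }
  n_perm <- check_count(n_perm, "n_perm")
  associated <- unique(as.character(gda_table$gene))
  obs_k <- sum(mod %in% associated)
  obs <- obs_k / length(mod)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(sample(uni, length(mod)) %in% associated)
    }, 0)
  })
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  structure(list(observed_fraction = obs, null_fractions = null, p = p,
                 n_associated = obs_k, n_module = length(mod),
                 n_perm = n_perm, seed = seed),
            class = "gda_perm_result")
}
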