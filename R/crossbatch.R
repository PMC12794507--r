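#' Jaccard similarity between two gene sets
#'
#' `|A ∩ B| / |A ∪ B|`; defined as 0 when both sets are empty. Symmetric,
#' bounded in \[0, 1\], and equal to 1 iff the (non-empty) sets coincide.
#'
#' @param a,b [gene_set()] objects or character vectors.
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(as_genes(a))
  b <- unique(as_genes(b))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Configuration for cross-batch program matching
#'
#' @param top_n genes taken per program, by spectra weight (default 200).
#' @param linkage hierarchical linkage rule (default `"average"`).
#' @param cut_height Jaccard-distance tree cut in (0, 1\] (default 0.8).
#' @param n_clusters optional override: cut the tree into a fixed number of
#'   clusters instead of at `cut_height`.
#' @param n_grid top-N values for the scree table (default seq(50, 400, 50)).
#' @return a `consensus_config` list.
#' @export
consensus_config <- function(top_n = 200L, linkage = "average",
                             cut_height = 0.8, n_clusters = NULL,
                             n_grid = seq(50L, 400L, by = 50L)) {
  cfg <- list(top_n = check_count(top_n, "top_n"),
              linkage = as.character(linkage),
              cut_height = check_fraction(cut_height, "cut_height"),
              n_clusters = if (is.null(n_clusters)) NULL else
                check_count(n_clusters, "n_clusters"),
              n_grid = sort(unique(as.integer(n_grid))))
  structure(cfg, class = "consensus_config")
}

# Top-N genes of one program by decreasing spectra weight; ties broken by
# lexicographic gene id for determinism.
program_top_genes <- function(weights, top_n) {
  ord <- order(-weights, names(weights))
  names(weights)[ord[seq_len(min(top_n, length(weights)))]]
}

#' Match programs across batches by Jaccard clustering
#'
#' Takes the top-N gene list of every program of every batch, computes all
#' pairwise Jaccard distances (1 - similarity), performs agglomerative
#' hierarchical clustering, cuts the tree, and keeps only clusters whose
#' members cover ALL batches. When a cluster holds several programs from
#' one batch their top-N lists are unioned before the cross-batch
#' intersection.
#'
#' @param program_sets named list (one element per batch) of `program_set`
#'   objects from [consensus_nmf()].
#' @param config a [consensus_config()].
#' @return list of `consensus_cluster` objects, each with `members`
#'   (data.frame batch, program), `batches_covered`, `gene_set` (the
#'   cross-batch intersection as a [gene_set()]), `scree` (from
#'   [refine_gene_set()]) and `top_genes` (per-batch unioned top-N lists).
#'   An empty list (with a warning) when no cluster covers all batches.
#' @export
match_programs <- function(program_sets, config = consensus_config()) {
  stopifnot(inherits(config, "consensus_config"))
  if (length(program_sets) < 2L) {
    stop("cross-batch matching needs at least 2 batches", call. = FALSE)
  }
  if (is.null(names(program_sets))) {
    names(program_sets) <- sprintf("B%d", seq_along(program_sets))
  }
  batches <- names(program_sets)
  # collate (batch, program) -> top-N gene list, batch/program order-stable
  units <- list()
  for (b in sort(batches)) {
    ps <- program_sets[[b]]
    progs <- rownames(ps$spectra)
    for (p in sort(progs)) {
      units[[paste(b, p, sep = "|")]] <-
        list(batch = b, program = p,
             genes = program_top_genes(ps$spectra[p, ], config$top_n))
    }
  }
  n <- length(units)
  sim <- matrix(1, n, n, dimnames = list(names(units), names(units)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- jaccard(units[[i]]$genes, units[[j]]$genes)
      sim[i, j] <- s
      sim[j, i] <- s
    }
  }
  dmat <- stats::as.dist(1 - sim)
  hc <- stats::hclust(dmat, method = config$linkage)
  cl <- if (is.null(config$n_clusters)) {
    stats::cutree(hc, h = config$cut_height)
  } else {
    stats::cutree(hc, k = min(config$n_clusters, n))
  }
  clusters <- list()
  for (k in sort(unique(cl))) {
    members <- units[cl == k]
    covered <- sort(unique(vapply(members, `[[`, "", "batch")))
    if (!setequal(covered, batches)) next
    # union top-N lists per batch, then intersect across batches
    per_batch <- lapply(split(members, vapply(members, `[[`, "", "batch")),
                        function(ms) unique(unlist(lapply(ms, `[[`, "genes"))))
    inter <- Reduce(intersect, per_batch)
    member_tab <- data.frame(
      batch = vapply(members, `[[`, "", "batch"),
      program = vapply(members, `[[`, "", "program"),
      stringsAsFactors = FALSE, row.names = NULL)
    cluster <- structure(list(
      members = member_tab,
      batches_covered = covered,
      top_genes = per_batch,
      gene_set = if (length(inter)) {
        gene_set(sort(inter), name = sprintf("consensus_%d", length(clusters) + 1L))
      } else NULL,
      jaccard = sim[names(members), names(members), drop = FALSE]),
      class = "consensus_cluster")
    clusters[[length(clusters) + 1L]] <- cluster
  }
  if (!length(clusters)) {
    warning("no program cluster covers all batches")
    return(list())
  }
  # attach the scree diagnostics from the member programs
  lapply(clusters, function(cluster) {
    cluster$scree <- refine_scree(program_sets, cluster, config$n_grid)
    cluster
  })
}

#' @export
print.consensus_cluster <- function(x, ...) {
  cat(sprintf("<consensus_cluster> %d programs over batches {%s}; intersection %d genes\n",
              nrow(x$members), paste(x$batches_covered, collapse = ","),
              if (is.null(x$gene_set)) 0L else length(x$gene_set$genes)))
  invisible(x)
}

# (N, intersection size) table over the top-N grid for one cluster.
refine_scree <- function(program_sets, cluster, n_grid) {
  sizes <- vapply(n_grid, function(N) {
    per_batch <- lapply(split(seq_len(nrow(cluster$members)), cluster$members$batch),
                        function(idx) {
      unique(unlist(lapply(idx, function(i) {
        b <- cluster$members$batch[i]
        p <- cluster$members$program[i]
        program_top_genes(program_sets[[b]]$spectra[p, ], N)
      })))
    })
    length(Reduce(intersect, per_batch))
  }, 0L)
  data.frame(n_input = n_grid, n_intersection = sizes)
}

#' Refine the consensus gene set of a cross-batch cluster
#'
#' For every N in the grid, intersects the per-batch top-N gene lists of
#' the cluster's member programs and reports the intersection size — the
#' scree table used to choose the input-gene threshold. The final gene set
#' uses `config$top_n`.
#'
#' @param program_sets the per-batch `program_set` list the cluster came
#'   from.
#' @param cluster a `consensus_cluster` from [match_programs()].
#' @param config a [consensus_config()]; `n_grid` drives the scree.
#' @return list with `gene_set` (a [gene_set()] at `top_n`) and `scree`
#'   (data.frame n_input, n_intersection).
#' @export
refine_gene_set <- function(program_sets, cluster, config = consensus_config()) {
  stopifnot(inherits(cluster, "consensus_cluster"),
            inherits(config, "consensus_config"))
  scree <- refine_scree(program_sets, cluster,
                        sort(unique(c(config$n_grid, config$top_n))))
  per_batch <- lapply(split(seq_len(nrow(cluster$members)), cluster$members$batch),
                      function(idx) {
    unique(unlist(lapply(idx, function(i) {
      b <- cluster$members$batch[i]
      p <- cluster$members$program[i]
      program_top_genes(program_sets[[b]]$spectra[p, ], config$top_n)
    })))
  })
  inter <- Reduce(intersect, per_batch)
  list(gene_set = if (length(inter)) gene_set(sort(inter), name = "consensus_module")
       else NULL,
       scree = scree)
}
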