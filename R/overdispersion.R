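#' Fit the CV2 ~ a1/mu + alpha0 overdispersion curve
#'
#' Models each gene's squared coefficient of variation (variance/mean^2) as
#' a function of its mean with a gamma-family generalized linear fit
#' (identity link) on 1/mu, i.e. `CV2 = a1/mu + alpha0`. Deviation of a
#' gene's observed CV2 above the fitted curve is assessed with a scaled
#' chi-square test on the variance ratio:
#' `(n-1) * CV2_obs / CV2_fit ~ chisq(n-1)` under the null, upper tail.
#'
#' The null curve is fit robustly in two passes: an initial gamma fit, then
#' a refit excluding genes whose variance ratio exceeds the `trim` quantile
#' (co-expression structure — identity programs, activity modules — would
#' otherwise inflate the curve and mask truly overdispersed genes), and
#' finally a quantile calibration of the ratio statistic: the `calib_q`
#' quantile of the scaled variance ratios is matched to the corresponding
#' chi-square null quantile, so the curve describes the typical
#' structure-free gene even when a substantial fraction of genes carries
#' real co-expression variance. Both steps are consistent under a pure
#' noise model.
#'
#' @param mat genes x cells (or genes x samples) numeric or sparse matrix.
#' @param min_mean genes with mean below this are excluded from the fit and
#'   ranked last.
#' @param trim quantile of the first-pass variance ratio above which genes
#'   are excluded from the second-pass fit (default 0.7).
#' @param calib_q quantile at which the ratio statistic is calibrated to
#'   its chi-square null (default 0.3).
#' @return a `cv2_fit`: data.frame with per-gene `mean`, `cv2`, `cv2_fit`,
#'   `p` (upper-tail deviation) plus attributes `a1`, `alpha0`.
#' @export
cv2_fit <- function(mat, min_mean = 1e-8, trim = 0.7, calib_q = 0.3) {
  mu <- Matrix::rowSums(mat) / ncol(mat)
  n <- ncol(mat)
  # E[x^2] via sparse-friendly sum of squares
  ex2 <- Matrix::rowSums(mat^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  v <- pmax(v, 0)
  cv2 <- ifelse(mu > min_mean, v / mu^2, NA_real_)
  use <- is.finite(cv2) & mu > min_mean
  if (sum(use) < 3L) stop("too few expressed genes for the CV2 fit", call. = FALSE)
  gam_fit <- function(idx) {
    X <- cbind(alpha0 = 1, a1 = 1 / mu[idx])
    fit <- statmod::glmgam.fit(X, cv2[idx])
    c(alpha0 = unname(fit$coefficients["alpha0"]),
      a1 = unname(fit$coefficients["a1"]))
  }
  co <- gam_fit(which(use))
  if (is.finite(co["a1"]) && co["a1"] > 0) {
    ratio1 <- cv2[use] / pmax(co["a1"] / mu[use] + co["alpha0"], .Machine$double.eps)
    keep <- which(use)[ratio1 <= quantile(ratio1, trim, na.rm = TRUE)]
    if (length(keep) >= 3L) {
      co2 <- tryCatch(gam_fit(keep), error = function(e) co)
      if (is.finite(co2["a1"]) && co2["a1"] > 0) co <- co2
    }
  }
  a1 <- co[["a1"]]
  alpha0 <- co[["alpha0"]]
  degenerate <- !is.finite(a1) || a1 <= 0
  if (degenerate) {
    warning("degenerate CV2 fit (a1 <= 0); ranking by raw CV2 residual")
    cv2_hat <- rep(mean(cv2[use]), length(mu))
  } else {
    cv2_hat <- a1 / mu + alpha0
    # calibrate at a low quantile, robust to a large elevated fraction
    s <- quantile((n - 1) * cv2[use] / cv2_hat[use], calib_q, na.rm = TRUE,
                  names = FALSE) / stats::qchisq(calib_q, df = n - 1)
    if (is.finite(s) && s > 0) cv2_hat <- cv2_hat * s
  }
  cv2_hat <- pmax(cv2_hat, .Machine$double.eps)
  p <- rep(NA_real_, length(mu))
  if (degenerate) {
    # fall back: pseudo-p from the residual rank so downstream ordering works
    resid <- cv2 - cv2_hat
    p[use] <- 1 - rank(resid[use]) / (sum(use) + 1)
  } else {
    p[use] <- pchisq((n - 1) * cv2[use] / cv2_hat[use], df = n - 1,
                     lower.tail = FALSE)
  }
  out <- data.frame(gene = rownames(mat), mean = as.numeric(mu),
                    cv2 = as.numeric(cv2), cv2_fit = as.numeric(cv2_hat),
                    p = p, stringsAsFactors = FALSE)
  attr(out, "a1") <- a1
  attr(out, "alpha0") <- alpha0
  attr(out, "degenerate") <- degenerate
  class(out) <- c("cv2_fit", "data.frame")
  out
}

#' Select overdispersed genes by CV2 deviation significance
#'
#' Ranks genes by the upper-tail significance of their CV2 above the fitted
#' `a1/mu + alpha0` curve (ties broken by smaller p, then lexicographic gene
#' id for determinism) and returns the top `n_top` as the discovery input.
#'
#' @param counts a [count_matrix()] or genes x cells matrix.
#' @param n_top number of genes to keep (default 2000).
#' @return list with `genes` (a [gene_set()], ranked) and `fit` (the
#'   [cv2_fit()] table).
#' @export
select_overdispersed <- function(counts, n_top = 2000L) {
  mat <- if (inherits(counts, "count_matrix")) counts$values else counts
  n_top <- check_count(n_top, "n_top")
  fit <- cv2_fit(mat)
  expressed <- which(is.finite(fit$p))
  if (n_top > length(expressed)) {
    stop(sprintf("n_top = %d exceeds the %d expressed genes",
                 n_top, length(expressed)), call. = FALSE)
  }
  ord <- expressed[order(fit$p[expressed], fit$gene[expressed])]
  top <- ord[seq_len(n_top)]
  list(genes = gene_set(fit$gene[top], name = sprintf("overdispersed_top%d", n_top),
                        weights = -log10(pmax(fit$p[top], .Machine$double.xmin))),
       fit = fit)
}

#' Select highly variable control genes by CV2 rank
#'
#' Thin wrapper over [select_overdispersed()] used as the unsupervised
#' control feature set in disease classification: the same CV2 machinery,
#' with `n_genes` defaulting to the module size so feature counts match.
#'
#' @param mat genes x samples matrix or [count_matrix()].
#' @param n_genes number of genes to return.
#' @return a [gene_set()].
#' @export
cv2_select <- function(mat, n_genes = 61L) {
  sel <- select_overdispersed(mat, n_top = n_genes)
  sel$genes$name <- sprintf("cv2_top%d", length(sel$genes$genes))
  sel$genes
}
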