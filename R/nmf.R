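# Single NMF replicate: multiplicative updates, Frobenius objective.
# V is cells x genes (dense or sparse); returns usages U (cells x K) and
# spectra S (K x genes). The update never increases the objective, which
# test-discovery asserts per iteration on small instances.
nmf_fit <- function(V, K, max_iter = 200L, tol = 1e-4, seed = 1L,
                    track_objective = FALSE) {
  n <- nrow(V)
  m <- ncol(V)
  stopifnot(K >= 1L, K <= min(n, m))
  eps <- .Machine$double.eps
  scale0 <- sqrt(mean(as.numeric(Matrix::rowSums(V)) / m) / K + eps)
  init <- with_seed(seed, list(U = matrix(runif(n * K), n, K) * scale0,
                               S = matrix(runif(K * m), K, m) * scale0))
  U <- init$U
  S <- init$S
  normV2 <- sum(V * V)
  objective <- function(U, S) {
    TUV <- as.matrix(Matrix::t(Matrix::t(V) %*% U))  # K x genes as t(U) V
    normV2 - 2 * sum(TUV * S) + sum(crossprod(U) * tcrossprod(S))
  }
  obj <- objective(U, S)
  trace <- if (track_objective) obj else NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    VSt <- as.matrix(V %*% Matrix::t(S))             # n x K
    U <- U * VSt / (U %*% tcrossprod(S) + eps)
    TUV <- as.matrix(Matrix::t(Matrix::t(V) %*% U))  # K x m
    S <- S * TUV / (crossprod(U) %*% S + eps)
    obj_new <- normV2 - 2 * sum(TUV * S) + sum(crossprod(U) * tcrossprod(S))
    if (track_objective) trace <- c(trace, obj_new)
    if (!is.finite(obj_new)) {
      return(list(U = U, S = S, objective = obj_new, converged = FALSE,
                  finite = FALSE, trace = trace))
    }
    if (abs(obj - obj_new) <= tol * max(abs(obj), eps)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(U = U, S = S, objective = obj, converged = converged, finite = TRUE,
       trace = trace)
}

# Unit-L2-normalize rows, guarding all-zero rows.
normalize_rows_l2 <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

# Nonnegative least-squares refit of usages against fixed consensus spectra.
refit_usages_nnls <- function(V, spectra) {
  A <- t(spectra)  # genes x K
  U <- t(apply(as.matrix(V), 1L, function(v) pracma::lsqnonneg(A, v)$x))
  if (nrow(spectra) == 1L) U <- matrix(as.numeric(U), ncol = 1L)
  U
}
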