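# Internal numeric helpers shared across modules.

# Exact Euclidean k-nearest-neighbour search of `query` rows against `ref`
# rows, computed blockwise with the squared-norm expansion
# |x - y|^2 = |x|^2 - 2<x,y> + |y|^2 (clipped at 0). Ties are broken by
# reference row index; duplicated reference points yield exactly equal
# distances, so the tie-break is well defined. Returns k columns of indices
# and ascending distances.
.knn_euclidean <- function(ref, query, k, exclude_self = FALSE,
                           block = 512L) {
  ref <- as.matrix(ref)
  query <- as.matrix(query)
  n_ref <- nrow(ref)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k_eff <- k + as.integer(exclude_self)
  if (k_eff > n_ref) stop("k exceeds the number of reference cells", call. = FALSE)
  nq <- nrow(query)
  idx <- matrix(NA_integer_, nq, k)
  dst <- matrix(NA_real_, nq, k)
  rn2 <- rowSums(ref * ref)
  for (start in seq(1, nq, by = block)) {
    rows <- start:min(start + block - 1L, nq)
    Q <- query[rows, , drop = FALSE]
    D2 <- matrix(rn2, length(rows), n_ref, byrow = TRUE) -
      2 * tcrossprod(Q, ref) + rowSums(Q * Q)
    for (i in seq_along(rows)) {
      d2 <- pmax(D2[i, ], 0)
      ord <- order(d2, seq_len(n_ref))[seq_len(k_eff)]
      if (exclude_self) ord <- ord[-1L]
      idx[rows[i], ] <- ord
      dst[rows[i], ] <- sqrt(d2[ord])
    }
  }
  list(index = idx, dist = dst)
}

# Top-d right singular vectors of a centered/scaled matrix, always exact:
# LAPACK svd when the gene space is small, symmetric eigendecomposition of
# the p x p crossprod otherwise (cheaper than a full svd when n >> d and
# p is a few thousand). Randomized sketches are deliberately not used —
# near-degenerate tail eigenvalues (ubiquitous in noisy count data) make
# them drop individual directions from the top-d subspace.
.pca_rotation <- function(X, d, exact_limit = 600L) {
  p <- ncol(X)
  if (p <= exact_limit) {
    return(svd(X, nu = 0, nv = d)$v)
  }
  ev <- eigen(crossprod(X), symmetric = TRUE)
  ev$vectors[, seq_len(d), drop = FALSE]
}

# Tie-corrected Wilcoxon rank-sum (Mann-Whitney) statistics for every column
# of X between mask==TRUE and mask==FALSE cells. Normal approximation, no
# continuity correction. Returns U, AUC, z and two-sided p per gene.
.rank_sum_stats <- function(X, mask) {
  X <- as.matrix(X)
  n1 <- sum(mask)
  n2 <- sum(!mask)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  n <- n1 + n2
  U <- numeric(ncol(X))
  sig2 <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    U[j] <- sum(r[mask]) - n1 * (n1 + 1) / 2
    tt <- table(X[, j])
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sig2[j] <- n1 * n2 / 12 * ((n + 1) - tie_term)
  }
  mu <- n1 * n2 / 2
  z <- ifelse(sig2 > 0, (U - mu) / sqrt(sig2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(p, 1)
  list(U = U, auc = U / (n1 * n2), z = z, p = p)
}

# coerce any matrix-like input to dgCMatrix
.as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  x
}

.dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

.stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
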