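## Decentralized two-stage PCA: local SVD-based reduction, column
## normalization, the serial round-robin subspace merge (GlobalPCA), and
## the recursive clustered parallel variant (pGlobalPCA). The merge works
## because stacking singular-value-scaled eigenvectors preserves the data
## covariance: P P' = X X' when no rank truncation occurs, so reducing the
## column-wise stack [P' P(j-1)] reduces the sum of site covariances.

#' Local PCA reduction of one data block
#'
#' Computes the thin SVD `X = U S V'` and returns the first `k` components
#' as the eigen package `P = U^(k) S^(k)` (singular vectors scaled by
#' singular values) together with `U^(k)` and the singular values. `k` is
#' truncated to the numerical rank of `X` (relative singular value cutoff
#' `1e-10`). Column signs follow the convention that each column's
#' largest-magnitude entry is positive.
#'
#' For tall thin matrices the SVD is computed from the eigendecomposition
#' of the smaller Gram matrix, which is what makes voxel-dimension inputs
#' (d in the thousands) cheap.
#'
#' @param X numeric matrix, voxels x columns.
#' @param k requested rank (>= 1).
#' @param tol relative singular value cutoff for rank detection.
#' @return an `eigen_package`: list with `P` (d x k'), `U`, `sigma`, and the
#'   effective rank `k`.
#' @examples
#' ep <- local_pca(diag(3), 2)
#' ep$sigma
#' @export
local_pca <- function(X, k, tol = 1e-10) {
  X <- as.matrix(X)
  if (k <= 0) stop("k must be positive")
  d <- nrow(X)
  n <- ncol(X)
  if (all(X == 0)) stop("all-zero matrix has no principal components")
  if (min(d, n) <= 512) {
    s <- svd(X)
    sv <- s$d
    Ufull <- s$u
  } else if (n <= d) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    sv <- sqrt(pmax(e$values, 0))
    rk0 <- sum(sv > tol * sv[1])
    Ufull <- X %*% sweep(e$vectors[, seq_len(rk0), drop = FALSE], 2,
                         sv[seq_len(rk0)], "/")
    sv <- sv[seq_len(rk0)]
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    sv <- sqrt(pmax(e$values, 0))
    rk0 <- sum(sv > tol * sv[1])
    Ufull <- e$vectors[, seq_len(rk0), drop = FALSE]
    sv <- sv[seq_len(rk0)]
  }
  rk <- sum(sv > tol * sv[1])
  kk <- as.integer(min(k, rk))
  U <- fix_column_signs(Ufull[, seq_len(kk), drop = FALSE])
  sigma <- sv[seq_len(kk)]
  structure(
    list(P = sweep(U, 2, sigma, "*"), U = U, sigma = sigma, k = kk),
    class = "eigen_package"
  )
}

#' @export
print.eigen_package <- function(x, ...) {
  cat("eigen_package: ", nrow(x$P), " x ", x$k,
      " (sigma ", signif(x$sigma[1], 4), " .. ",
      signif(x$sigma[x$k], 4), ")\n", sep = "")
  invisible(x)
}

#' Normalize the leading columns of a matrix
#'
#' Returns the first `r'` columns of `P`, each scaled to unit Euclidean
#' norm, preserving order.
#'
#' @param P numeric matrix.
#' @param r_prime number of leading columns to keep (<= ncol(P)).
#' @return d x r' matrix with unit-norm columns.
#' @examples
#' normalize_top_columns(cbind(c(3, 4)), 1)
#' @export
normalize_top_columns <- function(P, r_prime) {
  P <- as.matrix(P)
  if (r_prime > ncol(P)) stop("r' exceeds the number of columns")
  P <- P[, seq_len(r_prime), drop = FALSE]
  nrm <- sqrt(colSums(P^2))
  if (any(nrm < 1e-300)) stop("degenerate component: zero-norm column")
  sweep(P, 2, nrm, "/")
}

## Round-robin reduction over a list of items, each
## list(site = index, data = matrix). Walks the list in order, sending each
## intermediate eigen package over the channel and stacking it with the
## next site's local reduction. Returns the final (unnormalized) package.
serial_reduce <- function(cons, items, k) {
  p <- local_pca(items[[1]]$data, k)
  if (length(items) >= 2) {
    for (j in 2:length(items)) {
      send(cons, "eigen_package", p$P,
           src = items[[j - 1]]$site, dst = items[[j]]$site)
      pj <- local_pca(items[[j]]$data, k)
      kk <- min(max(pj$k, ncol(p$P)), ncol(pj$P) + ncol(p$P))
      p <- local_pca(cbind(pj$P, p$P), kk)
    }
  }
  p
}

## Items for the consortium in pi order.
consortium_items <- function(cons, data_key) {
  lapply(cons$order, function(i) list(site = i, data = site_data(cons, i, data_key)))
}

#' Serial decentralized PCA (round-robin subspace merge)
#'
#' Sites are visited in the consortium's random order; each site reduces
#' its own data, stacks the incoming eigen package column-wise with its own
#' reduction, reduces the stack, and forwards the result. Exactly `s - 1`
#' eigen-package messages cross the channel. The terminal (aggregator)
#' site normalizes the top `r` columns.
#'
#' @param cons a `consortium` whose sites hold data under `data_key`.
#' @param r final number of global spatial eigenvectors.
#' @param k working rank at each hop (`k >= r`).
#' @param data_key which per-site matrix to reduce: `"data"` for raw
#'   concatenated subjects or the name of a stored derived matrix (e.g.
#'   `"Xpre"` after [preprocess_subject()]).
#' @return d x r' matrix of unit-norm global spatial eigenvectors
#'   (`r' < r` only under rank collapse, with a warning).
#' @export
global_pca <- function(cons, r, k, data_key = "data") {
  if (k < r) stop("working rank k must be >= final rank r")
  p <- serial_reduce(cons, consortium_items(cons, data_key), k)
  rr <- min(r, p$k)
  if (rr < r) warning("rank collapsed to ", rr, " (< r = ", r, ")")
  normalize_top_columns(p$P, rr)
}

## Contiguous partition of s items into floor(s / C) clusters of size C,
## remainder folded into the last cluster.
partition_sites <- function(s, C) {
  K <- s %/% C
  lapply(seq_len(K), function(c) {
    a <- (c - 1L) * C + 1L
    b <- if (c == K) s else c * C
    a:b
  })
}

## Recursive clustered reduction. Items within a cluster are merged
## serially; cluster results become the items of the next level. The
## scheduling of clusters is irrelevant to the result (they are
## independent), so a sequential loop is a faithful simulation.
parallel_reduce <- function(cons, items, k, C, B) {
  s <- length(items)
  if (s == 1) return(local_pca(items[[1]]$data, k))
  K <- s %/% C
  if (s <= C || K <= B) return(serial_reduce(cons, items, k))
  clusters <- partition_sites(s, C)
  merged <- lapply(clusters, function(ix) {
    p <- parallel_reduce(cons, items[ix], k, C, B)
    list(site = items[[ix[length(ix)]]]$site, data = p$P)
  })
  parallel_reduce(cons, merged, k, C, B)
}

#' Parallel decentralized PCA (recursive clustered merge)
#'
#' Splits the consortium into clusters of size `C`, merges each cluster
#' with the serial round-robin scheme (these merges are independent and
#' could run concurrently), then recursively merges the cluster results
#' until a single eigen package reaches the final aggregator, which
#' normalizes the top `r` columns. With `C >= s` (or `floor(s/C) <= B`)
#' the code path is identical to [global_pca()].
#'
#' @inheritParams global_pca
#' @param C cluster size (>= 2).
#' @param B base number of clusters below which the merge is serial.
#' @return d x r' matrix of unit-norm global spatial eigenvectors.
#' @export
parallel_global_pca <- function(cons, r, k, C, B = 1, data_key = "data") {
  if (C < 2) stop("cluster size C must be >= 2")
  if (B < 1) stop("base cluster count B must be >= 1")
  if (k < r) stop("working rank k must be >= final rank r")
  p <- parallel_reduce(cons, consortium_items(cons, data_key), k, C, B)
  rr <- min(r, p$k)
  if (rr < r) warning("rank collapsed to ", rr, " (< r = ", r, ")")
  normalize_top_columns(p$P, rr)
}

#' Pooled PCA reference
#'
#' Centralized counterpart of [global_pca()]: one SVD of the column-wise
#' concatenation of all site data, top-`r` left singular vectors normalized
#' the same way. Used as the equivalence oracle in tests and experiments.
#'
#' @param X pooled matrix (voxels x total columns).
#' @param r number of components.
#' @return d x r matrix with unit-norm columns.
#' @export
pooled_pca <- function(X, r) {
  p <- local_pca(X, r)
  normalize_top_columns(p$P, min(r, p$k))
}
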