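## Internal numerical helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's RNG stream. All user-facing randomness in the package flows
#' through this helper, which makes every operation reproducible from its
#' `seed` argument alone.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

## Unit-variance Laplacian (double-exponential) deviates via inverse CDF.
## scale b = 1/sqrt(2) gives Var = 2 b^2 = 1.
rlaplace <- function(n, scale = 1 / sqrt(2)) {
  u <- stats::runif(n, -0.5, 0.5)
  -scale * sign(u) * log1p(-2 * abs(u))
}

## Moore-Penrose pseudo-inverse via SVD with a relative tolerance.
pinv_svd <- function(X, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) stop("matrix is numerically zero; pseudo-inverse undefined")
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Numerical rank with the package-wide relative singular value cutoff.
matrix_rank <- function(X, tol = 1e-10) {
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[1] == 0) return(0L)
  sum(d > tol * d[1])
}

#' Vectorize / devectorize the upper triangle of a symmetric matrix
#'
#' Connectivity matrices are passed to clustering as their strict upper
#' triangle in column-major order. `devec_upper` reverses the mapping,
#' restoring a symmetric matrix with the given diagonal.
#'
#' @param M symmetric matrix.
#' @param v vector of length `r (r - 1) / 2`.
#' @param diag value placed on the reconstructed diagonal.
#' @return `vec_upper`: a numeric vector; `devec_upper`: a symmetric matrix.
#' @examples
#' v <- vec_upper(diag(3))
#' devec_upper(v, diag = 1)
#' @export
vec_upper <- function(M) {
  M[upper.tri(M)]
}

#' @rdname vec_upper
#' @export
devec_upper <- function(v, diag = 1) {
  p <- length(v)
  r <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(r - round(r)) > 1e-8) {
    stop("length ", p, " is not r(r-1)/2 for integer r")
  }
  r <- as.integer(round(r))
  M <- matrix(0, r, r)
  M[upper.tri(M)] <- v
  M <- M + t(M)
  diag(M) <- diag
  M
}

## Principal angles (radians) between the column spaces of A and B.
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1))
}

## Row-standardize X so that tcrossprod(xs(X), xs(C)) is the Pearson
## correlation between rows; rows with zero variance raise an error unless
## zero_ok, in which case they become all-zero rows (correlation 0).
row_standardize <- function(X, zero_ok = FALSE) {
  X <- as.matrix(X)
  ctr <- X - rowMeans(X)
  ss <- sqrt(rowSums(ctr^2))
  bad <- ss < 1e-300
  if (any(bad)) {
    if (!zero_ok) stop("zero-variance row encountered in correlation computation")
    ss[bad] <- 1
    ctr[bad, ] <- 0
  }
  ctr / ss
}

## Pearson correlation between every row of X and every row of C.
cor_rows <- function(X, C, zero_ok = FALSE) {
  tcrossprod(row_standardize(X, zero_ok), row_standardize(C, zero_ok))
}

## Fix SVD/ICA sign ambiguity: make each column's largest-magnitude entry
## positive. Returns the sign vector as an attribute-free side product.
fix_column_signs <- function(U) {
  sg <- apply(U, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  sweep(U, 2, sg, "*")
}
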