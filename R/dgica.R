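## Decentralized group spatial ICA: per-subject preprocessing, two-stage
## decentralized PCA, whitening and infomax ICA at the aggregator,
## broadcast of the estimated spatial maps, and GICA1 back-reconstruction
## of subject timecourses and maps.

#' Preprocess one subject before group PCA
#'
#' Removes column means (each timepoint's mean across voxels) and then
#' reduces and normalizes the temporal dimension: the subject matrix is
#' replaced by the first `k1` singular-value-scaled left singular vectors,
#' rescaled to unit norm. The result is a voxels x k1 matrix whose Gram
#' matrix has unit diagonal.
#'
#' @param X_im subject matrix, voxels x timepoints.
#' @param k1 subject-level rank (field default 120 for 162-volume runs).
#' @return voxels x k1' matrix with unit-norm columns; `k1' < k1` only when
#'   the centered matrix has lower rank (with a warning).
#' @export
preprocess_subject <- function(X_im, k1) {
  X <- as.matrix(X_im)
  X <- sweep(X, 2, colMeans(X), "-")
  p <- local_pca(X, k1)
  if (p$k < k1) warning("subject rank ", p$k, " below requested k1 = ", k1)
  normalize_top_columns(p$P, p$k)
}

#' Whiten the columns of a matrix
#'
#' Centers columns and applies the symmetric (ZCA) whitening transform so
#' that the sample covariance of the output columns is the identity. The
#' transform and its inverse are returned for un-whitening.
#'
#' @param U matrix with full column rank (voxels x r).
#' @return list with `Uw` (whitened matrix), `K` (whitening matrix, applied
#'   on the right), `Kinv`, and `center` (column means).
#' @export
whiten <- function(U) {
  U <- as.matrix(U)
  ctr <- colMeans(U)
  Uc <- sweep(U, 2, ctr, "-")
  C <- stats::cov(Uc)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values)) {
    stop("rank-deficient input: cannot whiten")
  }
  K <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  Kinv <- e$vectors %*% (t(e$vectors) * sqrt(e$values))
  list(Uw = Uc %*% K, K = K, Kinv = Kinv, center = ctr)
}

#' Infomax ICA (natural-gradient, logistic nonlinearity)
#'
#' Maximum-likelihood ICA for super-Gaussian sources, written from the
#' natural-gradient update `W <- W + lr (I + (1 - 2 y) u') W` with
#' `u = W x` and `y = logistic(u)`, applied over shuffled mini-blocks of
#' rows. The rows of the whitened input are treated as samples, so the
#' estimated sources are independent across voxels (spatial ICA). The
#' learning rate anneals by `anneal` whenever the angle between successive
#' weight updates exceeds 60 degrees; convergence is declared when the
#' relative weight change after a full pass drops below `tol`. Fully
#' deterministic given `seed`.
#'
#' @param Uw whitened matrix, voxels x r (rows are samples).
#' @param lr initial learning rate; default `0.015 / log(r)`.
#' @param max_iter maximum full passes over the data.
#' @param tol relative weight-change convergence threshold.
#' @param seed integer seed (controls block shuffling).
#' @param anneal learning-rate annealing factor.
#' @return an `ica_result`: list with `W` (r x r, such that the estimated
#'   spatial components are `A_hat = Uw %*% W`), `A_hat`, `iterations`,
#'   `converged`, `lr_final`, and `variant = "infomax"`.
#' @export
infomax_ica <- function(Uw, lr = NULL, max_iter = 1000, tol = 1e-6,
                        seed = 1, anneal = 0.9) {
  X <- t(as.matrix(Uw))            # r x n, samples as columns
  r <- nrow(X)
  if (r < 2) stop("need at least 2 components for ICA")
  n <- ncol(X)
  if (is.null(lr)) lr <- 0.015 / log(r)
  block <- max(8L, min(as.integer(ceiling(sqrt(n / 3))), n))
  W <- diag(r)
  Ir <- diag(r)
  prev_delta <- NULL
  converged <- FALSE
  iters <- 0L
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      W_old <- W
      perm <- sample.int(n)
      start <- 1L
      while (start <= n) {
        idx <- perm[start:min(start + block - 1L, n)]
        u <- W %*% X[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        nb <- length(idx)
        W <- W + lr * ((nb * Ir + (1 - 2 * y) %*% t(u)) %*% W) / nb
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
          # blow-up: restart this pass from the last stable weights
          W <- W_old
          lr <- lr * 0.5
          break
        }
        start <- start + block
      }
      delta <- W - W_old
      if (!is.null(prev_delta)) {
        num <- sum(delta * prev_delta)
        den <- sqrt(sum(delta^2) * sum(prev_delta^2))
        if (den > 0 && num / den < cos(60 * pi / 180)) lr <- lr * anneal
      }
      prev_delta <- delta
      iters <- it
      if (sqrt(sum(delta^2) / sum(W^2)) < tol) {
        converged <- TRUE
        break
      }
    }
  })
  if (!converged) {
    warning("infomax ICA did not converge in ", max_iter, " passes")
  }
  W_out <- t(W)                    # A_hat = Uw %*% W_out
  structure(
    list(W = W_out, A_hat = as.matrix(Uw) %*% W_out, iterations = iters,
         converged = converged, lr_final = lr, variant = "infomax"),
    class = "ica_result"
  )
}

#' Fixed-point kurtosis ICA
#'
#' Alternative ICA backend: symmetric fixed-point iteration maximizing
#' kurtosis (`g(u) = u^3`) with symmetric decorrelation, on the same
#' rows-as-samples convention as [infomax_ica()]. Mainly used to compare
#' ICA backends in [run_experiments()].
#'
#' @inheritParams infomax_ica
#' @return an `ica_result` with `variant = "fastica_kurtosis"`.
#' @export
fastica_kurtosis <- function(Uw, max_iter = 200, tol = 1e-9, seed = 1) {
  X <- t(as.matrix(Uw))
  r <- nrow(X)
  if (r < 2) stop("need at least 2 components for ICA")
  n <- ncol(X)
  sym_decorr <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    (e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300)))) %*% W
  }
  W <- with_seed(seed, matrix(stats::rnorm(r * r), r, r))
  W <- sym_decorr(W)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    U <- W %*% X
    Wn <- (U^3 %*% t(X)) / n - 3 * W
    Wn <- sym_decorr(Wn)
    # compare up to row sign
    chg <- 1 - min(abs(rowSums(Wn * W)))
    W <- Wn
    iters <- it
    if (chg < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("fixed-point ICA did not converge")
  W_out <- t(W)
  structure(
    list(W = W_out, A_hat = as.matrix(Uw) %*% W_out, iterations = iters,
         converged = converged, lr_final = NA_real_,
         variant = "fastica_kurtosis"),
    class = "ica_result"
  )
}

#' Registry of ICA backends
#'
#' @param name `"infomax"` (default pipeline backend) or
#'   `"fastica_kurtosis"`.
#' @return the backend function.
#' @export
ica_backend <- function(name = c("infomax", "fastica_kurtosis")) {
  switch(match.arg(name),
         infomax = infomax_ica,
         fastica_kurtosis = fastica_kurtosis)
}

#' @export
print.ica_result <- function(x, ...) {
  cat("ica_result (", x$variant, "): ", ncol(x$W), " components, ",
      x$iterations, " iterations, converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Decentralized group ICA
#'
#' Runs the full decentralized group ICA protocol on a consortium: each
#' site preprocesses its subjects locally ([preprocess_subject()]) and
#' concatenates them temporally; decentralized PCA (serial or parallel)
#' reduces the cross-site data to `r` global spatial eigenvectors at the
#' aggregator; the aggregator whitens them and runs ICA; the estimated
#' spatial maps `A_hat` are broadcast back to all other sites. Only eigen
#' packages and the `A_hat` broadcast cross the channel.
#'
#' @param cons a `consortium` holding raw subjects.
#' @param r number of independent components (field default 100).
#' @param k1 subject-level PCA rank (field default 120).
#' @param k2 site-level working rank; defaults to `5 * r` and warns when
#'   smaller.
#' @param ica_variant ICA backend name, see [ica_backend()].
#' @param pca_variant `"serial"` ([global_pca()]) or `"parallel"`
#'   ([parallel_global_pca()]).
#' @param ica_seed seed passed to the ICA backend.
#' @param C,B cluster sizes for the parallel PCA variant.
#' @param max_iter,tol passed to the ICA backend.
#' @return an `ica_result` with additional fields `U` (global
#'   eigenvectors), `whitening`, and `r`; every site's store gains `A_hat`.
#' @export
run_dgica <- function(cons, r, k1 = 120, k2 = 5 * r,
                      ica_variant = "infomax", pca_variant = c("serial", "parallel"),
                      ica_seed = 1, C = 2, B = 1, max_iter = 1000, tol = 1e-6) {
  pca_variant <- match.arg(pca_variant)
  if (k2 < 5 * r) warning("k2 = ", k2, " is below the recommended 5 * r")
  s <- length(cons$sites)
  for (i in seq_len(s)) {
    st <- site_store(cons, i)
    pre <- lapply(cons$sites[[i]]$subjects, preprocess_subject, k1 = k1)
    st$Xpre <- do.call(cbind, pre)
  }
  U <- if (pca_variant == "serial") {
    global_pca(cons, r, k2, data_key = "Xpre")
  } else {
    parallel_global_pca(cons, r, k2, C = C, B = B, data_key = "Xpre")
  }
  wh <- whiten(U)
  backend <- ica_backend(ica_variant)
  fit <- backend(wh$Uw, max_iter = max_iter, tol = tol, seed = ica_seed)
  fit$U <- U
  fit$whitening <- wh
  fit$r <- ncol(U)
  agg <- cons$aggregator
  for (i in setdiff(seq_len(s), agg)) {
    send(cons, "unmixing_maps", fit$A_hat, src = agg, dst = i)
  }
  for (i in seq_len(s)) {
    st <- site_store(cons, i)
    st$A_hat <- fit$A_hat
  }
  fit
}

#' Pooled group ICA reference
#'
#' Centralized counterpart of [run_dgica()]: identical per-subject
#' preprocessing, then a single pooled PCA of all subjects' preprocessed
#' data to `r` components, whitening, and the same seeded ICA backend.
#' Used as the decentralization-equivalence oracle.
#'
#' @param subjects list of subject matrices (voxels x timepoints).
#' @inheritParams run_dgica
#' @return an `ica_result` with fields `U` and `whitening`.
#' @export
pooled_gica <- function(subjects, r, k1 = 120, ica_variant = "infomax",
                        ica_seed = 1, max_iter = 1000, tol = 1e-6) {
  pre <- lapply(subjects, preprocess_subject, k1 = k1)
  U <- pooled_pca(do.call(cbind, pre), r)
  wh <- whiten(U)
  backend <- ica_backend(ica_variant)
  fit <- backend(wh$Uw, max_iter = max_iter, tol = tol, seed = ica_seed)
  fit$U <- U
  fit$whitening <- wh
  fit$r <- ncol(U)
  fit
}

#' GICA1 back-reconstruction of one subject
#'
#' Subject timecourses are the least-squares solution of
#' `A_hat S = X_im`, i.e. `S_hat = pinv(A_hat) X_im`; subject-specific
#' spatial maps are then `A_hat_im = X_im pinv(S_hat)`.
#'
#' @param A_hat group spatial maps, voxels x r (full column rank).
#' @param X_im subject matrix, voxels x timepoints.
#' @return a `subject_decomposition`: list with `S_hat` (r x timepoints)
#'   and `A_hat_im` (voxels x r).
#' @export
back_reconstruct <- function(A_hat, X_im) {
  A_hat <- as.matrix(A_hat)
  X_im <- as.matrix(X_im)
  S_hat <- tryCatch(
    solve(crossprod(A_hat), crossprod(A_hat, X_im)),
    error = function(e) {
      warning("rank-deficient spatial maps; using pseudo-inverse")
      pinv_svd(A_hat) %*% X_im
    }
  )
  if (matrix_rank(S_hat) < nrow(S_hat)) {
    warning("rank-deficient subject timecourses; using tolerance pseudo-inverse")
  }
  A_im <- X_im %*% pinv_svd(S_hat)
  structure(list(S_hat = S_hat, A_hat_im = A_im),
            class = "subject_decomposition")
}
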