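## Sliding-window connectivity: windowed Pearson correlation of
## back-reconstructed component timecourses, vectorized upper triangles,
## and exemplar-window selection at local maxima of the across-pair
## connectivity variance timecourse.

#' Sliding-window correlation of component timecourses
#'
#' Window `w` covers timepoints `w .. w + t` (`t + 1` samples), for
#' `w = 1 .. N - t`, so a 162-timepoint subject with `t = 22` yields 140
#' windows. Each window's Pearson correlation matrix across components is
#' vectorized as its strict upper triangle (length `r (r - 1) / 2`). A
#' component with zero variance inside a window contributes correlation 0
#' for its pairs, and the window index is recorded in the `flagged`
#' attribute.
#'
#' @param S_hat component timecourses, r x N.
#' @param t window size parameter (>= 2, < N); field default 22.
#' @return `(N - t) x (r (r - 1) / 2)` matrix, one window per row, with
#'   attributes `t`, `r`, and `flagged`.
#' @export
sliding_window_corr <- function(S_hat, t) {
  S_hat <- as.matrix(S_hat)
  r <- nrow(S_hat)
  N <- ncol(S_hat)
  if (t < 2) stop("window size t must be >= 2")
  if (t >= N) stop("window size t must be smaller than the timecourse length")
  nw <- N - t
  p <- r * (r - 1) / 2
  V <- matrix(0, nw, p)
  flagged <- integer(0)
  for (w in seq_len(nw)) {
    seg <- S_hat[, w:(w + t), drop = FALSE]
    sds <- apply(seg, 1, stats::sd)
    if (any(sds == 0)) {
      flagged <- c(flagged, w)
      Cw <- matrix(0, r, r)
      ok <- sds > 0
      if (sum(ok) >= 2) Cw[ok, ok] <- stats::cor(t(seg[ok, , drop = FALSE]))
    } else {
      Cw <- stats::cor(t(seg))
    }
    V[w, ] <- vec_upper(Cw)
  }
  attr(V, "t") <- t
  attr(V, "r") <- r
  attr(V, "flagged") <- flagged
  V
}

#' Select exemplar windows
#'
#' Computes, at each window, the variance of the windowed correlation
#' values across all component pairs, and returns the windows at strict
#' local maxima of this variance timecourse (`v(w) > v(w - 1)` and
#' `v(w) > v(w + 1)`; endpoints excluded). If no strict local maximum
#' exists (e.g. a monotone or constant timecourse) the single global
#' argmax window is returned instead. With `standardize_pairs = TRUE`
#' each pair's correlation values are standardized across windows first
#' (z-scoring per pair before taking the across-pair variance).
#'
#' @param V window stack entry from [sliding_window_corr()] (windows x
#'   pairs).
#' @param standardize_pairs standardize each pair across windows before
#'   computing the across-pair variance.
#' @return integer vector of 1-based exemplar window indices, strictly
#'   increasing.
#' @export
select_exemplars <- function(V, standardize_pairs = FALSE) {
  V <- as.matrix(V)
  if (nrow(V) < 3) stop("need at least 3 windows to select exemplars")
  if (standardize_pairs) {
    mu <- colMeans(V)
    sdv <- apply(V, 2, stats::sd)
    sdv[sdv == 0] <- 1
    V <- sweep(sweep(V, 2, mu, "-"), 2, sdv, "/")
  }
  v <- apply(V, 1, stats::var)
  n <- length(v)
  mid <- 2:(n - 1)
  is_max <- v[mid] > v[mid - 1] & v[mid] > v[mid + 1]
  idx <- mid[is_max]
  if (!length(idx)) idx <- which.max(v)
  sort(idx)
}

#' Back-reconstruct, window, and select exemplars across a consortium
#'
#' Local (no-communication) stage of the pipeline: every site
#' back-reconstructs each subject's timecourses from the broadcast group
#' maps, computes sliding-window correlations, and selects exemplar
#' windows. Results are stored in each site's store (`timecourses`,
#' `window_stacks`, `exemplar_idx`, `windows`, `exemplars`,
#' `window_index`) for the clustering stage.
#'
#' @param cons a `consortium` whose sites hold `A_hat` (after
#'   [run_dgica()]).
#' @param t window size parameter.
#' @param drop_first number of initial timepoints to drop from each
#'   subject's timecourses before windowing (real-data postprocessing;
#'   default 0 for synthetic data).
#' @return the consortium, invisibly; side effect is per-site storage.
#' @export
compute_windows <- function(cons, t, drop_first = 0) {
  for (i in seq_along(cons$sites)) {
    st <- site_store(cons, i)
    A_hat <- st$A_hat
    if (is.null(A_hat)) stop("site ", i, " has no spatial maps; run dgICA first")
    subs <- cons$sites[[i]]$subjects
    st$timecourses <- lapply(subs, function(X) {
      S <- back_reconstruct(A_hat, X)$S_hat
      if (drop_first > 0) S <- S[, -seq_len(drop_first), drop = FALSE]
      S
    })
    st$window_stacks <- lapply(st$timecourses, sliding_window_corr, t = t)
    st$exemplar_idx <- lapply(st$window_stacks, select_exemplars)
    st$windows <- do.call(rbind, st$window_stacks)
    st$exemplars <- do.call(rbind, Map(function(V, ix) V[ix, , drop = FALSE],
                                       st$window_stacks, st$exemplar_idx))
    st$window_index <- do.call(rbind, Map(
      function(nm, V) data.frame(site = i, subject = nm,
                                 window = seq_len(nrow(V))),
      names(st$window_stacks), st$window_stacks))
  }
  invisible(cons)
}
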