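## Synthetic data generators: unstructured Gaussian matrices for PCA
## equivalence experiments, and structured multi-subject spatial-ICA data
## whose timecourses switch among a small number of planted connectivity
## states, for end-to-end pipeline recovery tests.

#' Seeded i.i.d. standard normal matrix
#'
#' @param d,n dimensions.
#' @param seed integer seed.
#' @return a `d x n` matrix of N(0, 1) entries.
#' @examples
#' X <- gen_gaussian(100, 100, seed = 1)
#' @export
gen_gaussian <- function(d, n, seed = 1) {
  stopifnot(d >= 1, n >= 1)
  with_seed(seed, matrix(stats::rnorm(d * n), d, n))
}

## Draw k well-separated random correlation matrices of size r from a
## low-rank-factor + diagonal model; redraw until all pairwise correlation
## distances between vectorized upper triangles exceed min_sep.
random_state_centroids <- function(r, k, min_sep = 0.5, n_factors = 2,
                                   max_tries = 200) {
  for (try in seq_len(max_tries)) {
    cents <- lapply(seq_len(k), function(j) {
      B <- matrix(stats::rnorm(r * n_factors), r, n_factors)
      stats::cov2cor(tcrossprod(B) + diag(r) * 0.6)
    })
    if (k == 1) return(cents)
    V <- do.call(rbind, lapply(cents, vec_upper))
    dm <- 1 - cor_rows(V, V)
    if (min(dm[upper.tri(dm)]) >= min_sep) return(cents)
  }
  stop("failed to draw ", k, " state centroids separated by >= ", min_sep)
}

#' Generate a planted-state multi-subject dataset
#'
#' Each subject's data follow the linear spatial mixing model
#' `X = A S + E`: the columns of `A` (voxels x r) are independent
#' unit-variance Laplacian spatial sources (super-Gaussian, so infomax ICA
#' is identifiable), and the timecourses `S` (r x T) are piecewise-stationary
#' Gaussians whose correlation structure follows a hidden state sequence.
#' Each state is a planted r x r correlation matrix (a connectivity
#' "centroid"); within a state segment, timepoints are drawn as `L z` with
#' `L` the Cholesky factor of the state's correlation matrix. Segment
#' lengths are geometric with mean `dwell` timepoints. Sensor noise is
#' i.i.d. Gaussian with standard deviation `noise_sd`.
#'
#' @param d voxels.
#' @param n_subjects subjects (distributed over sites by
#'   [build_consortium()]).
#' @param n_time timepoints per subject.
#' @param r number of spatial components.
#' @param k_states number of planted connectivity states (>= 1).
#' @param dwell mean state-segment length in timepoints. Since sliding
#'   windows advance one timepoint at a time, this also approximates the
#'   mean dwell in windows. Default 60 keeps segments longer than the
#'   default window (22), so most windows are state-pure.
#' @param noise_sd sensor noise s.d. The sources are unit variance, so the
#'   per-entry signal variance is about `r`; the default 1 gives roughly
#'   10:1 signal-to-noise power at `r = 10`.
#' @param seed integer seed.
#' @param centroids optional list of `k_states` correlation matrices to
#'   plant instead of drawing them.
#' @param min_sep minimum pairwise correlation distance between drawn
#'   centroids.
#' @return list with `subjects` (list of d x n_time matrices) and `truth`,
#'   a `ground_truth` object holding `A`, `state_centroids`,
#'   `state_sequences` (per-subject per-timepoint labels), timecourses `S`,
#'   and the generator parameters.
#' @examples
#' gs <- gen_state_dataset(d = 200, n_subjects = 2, n_time = 60, r = 4,
#'                         k_states = 2, seed = 1)
#' dim(gs$subjects[[1]])
#' @export
gen_state_dataset <- function(d, n_subjects, n_time, r, k_states,
                              dwell = 60, noise_sd = 1, seed = 1,
                              centroids = NULL, min_sep = 0.5) {
  stopifnot(d >= r, n_subjects >= 1, n_time >= 2, r >= 2, k_states >= 1)
  if (!is.null(centroids)) {
    if (length(centroids) != k_states) {
      stop("k_states = ", k_states, " but ", length(centroids),
           " centroids supplied: non-identifiable setup")
    }
    lapply(centroids, function(C) {
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      if (any(abs(diag(C) - 1) > 1e-8) || min(ev) < -1e-8) {
        stop("planted centroids must be valid correlation matrices")
      }
    })
  }
  with_seed(seed, {
    if (is.null(centroids)) {
      centroids <- if (k_states == 1) {
        random_state_centroids(r, 1, min_sep = 0)
      } else {
        random_state_centroids(r, k_states, min_sep = min_sep)
      }
    }
    chols <- lapply(centroids, function(C) t(chol(C + diag(r) * 1e-10)))
    A <- matrix(rlaplace(d * r), d, r)
    subjects <- vector("list", n_subjects)
    S_list <- vector("list", n_subjects)
    seqs <- vector("list", n_subjects)
    for (m in seq_len(n_subjects)) {
      lab <- integer(0)
      state <- sample.int(k_states, 1)
      while (length(lab) < n_time) {
        len <- 1L + stats::rgeom(1, 1 / dwell)
        lab <- c(lab, rep(state, len))
        state <- if (k_states > 1) {
          sample(setdiff(seq_len(k_states), state), 1)
        } else state
      }
      lab <- lab[seq_len(n_time)]
      Z <- matrix(stats::rnorm(r * n_time), r, n_time)
      S <- matrix(0, r, n_time)
      for (st in unique(lab)) {
        idx <- which(lab == st)
        S[, idx] <- chols[[st]] %*% Z[, idx, drop = FALSE]
      }
      X <- A %*% S
      if (noise_sd > 0) X <- X + matrix(stats::rnorm(d * n_time, sd = noise_sd), d, n_time)
      subjects[[m]] <- X
      S_list[[m]] <- S
      seqs[[m]] <- lab
    }
    truth <- structure(
      list(A = A, state_centroids = centroids, state_sequences = seqs,
           S = S_list, d = d, r = r, k_states = k_states, n_time = n_time,
           dwell = dwell, noise_sd = noise_sd, seed = seed),
      class = "ground_truth"
    )
    list(subjects = subjects, truth = truth)
  })
}

#' Planted state label for each sliding window
#'
#' Window `w` spans timepoints `w .. w + t`; the window's label is the
#' majority planted state over those `t + 1` samples (ties broken by the
#' lowest state index).
#'
#' @param truth a `ground_truth` object.
#' @param t window size parameter (window covers `t + 1` timepoints).
#' @return list of integer label vectors, one per subject, length
#'   `n_time - t`.
#' @export
true_window_labels <- function(truth, t) {
  lapply(truth$state_sequences, function(lab) {
    nw <- length(lab) - t
    vapply(seq_len(nw), function(w) {
      tb <- tabulate(lab[w:(w + t)], nbins = truth$k_states)
      which.max(tb)
    }, 0L)
  })
}

#' Write subjects as flat matrix files
#'
#' One whitespace-delimited text file per subject (voxels x timepoints,
#' no headers), the format accepted by [load_subjects()].
#'
#' @param subjects list of matrices.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_subjects <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(subjects))
  for (m in seq_along(subjects)) {
    paths[m] <- file.path(dir, sprintf("subject_%03d.tsv", m))
    # %.17g so the written doubles round-trip bit-exactly
    txt <- apply(subjects[[m]], 1, function(row) {
      paste(sprintf("%.17g", row), collapse = "\t")
    })
    writeLines(txt, paths[m])
  }
  invisible(paths)
}
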