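## Decentralized K-means over windowed connectivity vectors, uniformly
## under correlation distance: multishot Lloyd's (count-weighted centroid
## averaging, pooled-exact), multishot gradient descent (count-weighted
## gradient averaging), single-shot merging of locally converged centroids,
## and the two-stage exemplar -> full-data protocol. Pooled reference
## implementations are provided as equivalence oracles.

#' Correlation distance
#'
#' `1 - Pearson correlation`, the distance used by every clustering stage
#' (assignment, merging, silhouette). Lies in `[0, 2]`.
#'
#' @param u,v numeric vectors of equal length (>= 3) with nonzero variance.
#' @return scalar distance.
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  if (length(u) < 3) stop("correlation distance needs vectors of length >= 3")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("zero-variance vector in correlation distance")
  }
  1 - stats::cor(u, v)
}

## Pairwise correlation-distance matrix between rows of X and rows of C.
cor_dist <- function(X, C) 1 - cor_rows(X, C)

## Nearest-centroid labels under correlation distance; ties broken by the
## lowest centroid index (max.col "first" on similarity).
assign_nearest <- function(X, C) {
  max.col(cor_rows(X, C), ties.method = "first")
}

## Per-cluster sums and counts of rows of X for k clusters.
cluster_sums <- function(X, labels, k) {
  counts <- tabulate(labels, nbins = k)
  sums <- matrix(0, k, ncol(X))
  nz <- which(counts > 0)
  for (j in nz) sums[j, ] <- colSums(X[labels == j, , drop = FALSE])
  list(sums = sums, counts = counts)
}

new_cluster_result <- function(C, labels, inertia, iterations, variant, k,
                               extra = list()) {
  structure(c(list(C = C, labels = labels, inertia = inertia,
                   iterations = iterations, variant = variant,
                   k = as.integer(k)),
              extra),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result (", x$variant, "): k = ", x$k, ", ",
      length(unlist(x$labels)), " points, ", x$iterations,
      " iterations, final inertia ", signif(utils::tail(x$inertia, 1), 6),
      "\n", sep = "")
  invisible(x)
}

#' Pooled Lloyd's K-means under correlation distance
#'
#' Centralized reference: nearest-centroid assignment by correlation
#' distance (ties to the lowest index), centroid update as the mean of
#' members, empty clusters re-seeded from the point farthest from its
#' assigned centroid, convergence when assignments stabilize. Every rule
#' matches the decentralized multishot Lloyd's implementation, which makes
#' the two trajectories identical on identical pooled data.
#'
#' @param X data matrix (points x features).
#' @param k number of clusters.
#' @param C_init k x features initial centroid matrix.
#' @param max_iter iteration cap.
#' @return a `cluster_result`.
#' @export
pooled_lloyd <- function(X, k, C_init, max_iter = 100) {
  X <- as.matrix(X)
  C <- as.matrix(C_init)
  if (nrow(C) != k) stop("C_init must have k rows")
  labels_prev <- rep(0L, nrow(X))
  inertia <- numeric(0)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    labels <- assign_nearest(X, C)
    D <- cor_dist(X, C)
    inertia <- c(inertia, sum(D[cbind(seq_len(nrow(X)), labels)]))
    cs <- cluster_sums(X, labels, k)
    Cnew <- C
    nz <- cs$counts > 0
    Cnew[nz, ] <- cs$sums[nz, , drop = FALSE] / cs$counts[nz]
    dmine <- D[cbind(seq_len(nrow(X)), labels)]
    for (j in which(!nz)) Cnew[j, ] <- X[which.max(dmine), ]
    iters <- it
    if (identical(labels, labels_prev)) break
    labels_prev <- labels
    C <- Cnew
  }
  new_cluster_result(C, labels_prev, inertia, iters, "pooled_lloyd", k)
}

## Collect per-site matrices under `data_key` in site order 1..s, together
## with the row bookkeeping. Used by decentralized variants for local
## access and by tests as the pooled oracle's input.
#' Stack per-site clustering inputs (evaluation helper)
#'
#' Concatenates each site's stored matrix (e.g. `"windows"` or
#' `"exemplars"`) in site order. This deliberately breaks decentralization
#' and exists only to feed pooled reference implementations and reports.
#'
#' @param cons a `consortium` after [compute_windows()].
#' @param data_key per-site stored matrix name.
#' @return one matrix with all sites' rows stacked.
#' @export
gather_windows <- function(cons, data_key = "windows") {
  do.call(rbind, lapply(seq_along(cons$sites), function(i) {
    site_data(cons, i, data_key)
  }))
}

## Shared multishot skeleton: per iteration the aggregator broadcasts
## centroids, sites assign locally and reply with local statistics, and
## `update` turns those into new centroids at the aggregator.
multishot_engine <- function(cons, data_key, k, C_init, max_iter, update,
                             variant, stop_on_stable_labels = TRUE) {
  s <- length(cons$sites)
  agg <- cons$aggregator
  Xs <- lapply(seq_len(s), function(i) site_data(cons, i, data_key))
  C <- as.matrix(C_init)
  if (nrow(C) != k) stop("C_init must have k rows")
  labels_prev <- lapply(Xs, function(X) rep(0L, nrow(X)))
  inertia <- numeric(0)
  iters <- 0L
  labels <- labels_prev
  for (it in seq_len(max_iter)) {
    for (i in setdiff(seq_len(s), agg)) send(cons, "centroids", C, agg, i)
    stats_list <- vector("list", s)
    for (i in seq_len(s)) {
      X <- Xs[[i]]
      lab <- assign_nearest(X, C)
      D <- cor_dist(X, C)
      dmine <- D[cbind(seq_len(nrow(X)), lab)]
      cs <- cluster_sums(X, lab, k)
      far <- which.max(dmine)
      st <- list(labels = lab, sums = cs$sums, counts = cs$counts,
                 inertia = sum(dmine), far_point = X[far, ],
                 far_dist = dmine[far], far_row = far)
      if (i != agg) {
        send(cons, "centroids", st$sums, i, agg)
        send(cons, "counts", st$counts, i, agg)
        send(cons, "scalar_stats", c(st$inertia, st$far_dist), i, agg)
      }
      stats_list[[i]] <- st
    }
    labels <- lapply(stats_list, `[[`, "labels")
    inertia <- c(inertia, sum(vapply(stats_list, `[[`, 0, "inertia")))
    res <- update(C, stats_list)
    iters <- it
    if (stop_on_stable_labels && identical(labels, labels_prev)) break
    labels_prev <- labels
    C <- res$C
    if (!is.null(res$stop) && res$stop) break
  }
  list(C = C, labels = labels, inertia = inertia, iterations = iters,
       variant = variant, Xs = Xs)
}

#' Multishot decentralized Lloyd's K-means
#'
#' At each iteration every site assigns its windows to the nearest
#' broadcast centroid (correlation distance) and sends per-cluster local
#' sums and member counts to the aggregator, which forms the
#' count-weighted average -- exactly the pooled Lloyd's centroid update.
#' With the same initialization the label trajectory is therefore
#' identical to [pooled_lloyd()] on the concatenated data. Globally empty
#' clusters are re-seeded from the globally farthest point (sites offer
#' their local farthest candidate). Converges when assignments stabilize.
#'
#' @param cons a `consortium` whose sites store clustering inputs under
#'   `data_key`.
#' @param data_key per-site stored matrix (`"windows"` or `"exemplars"`).
#' @param k number of clusters.
#' @param C_init k x features initial centroids.
#' @param max_iter iteration cap.
#' @return a `cluster_result`; `labels` is a list of per-site label
#'   vectors.
#' @export
multishot_lloyd <- function(cons, data_key, k, C_init, max_iter = 100) {
  update <- function(C, stats_list) {
    sums <- Reduce(`+`, lapply(stats_list, `[[`, "sums"))
    counts <- Reduce(`+`, lapply(stats_list, `[[`, "counts"))
    Cnew <- C
    nz <- counts > 0
    Cnew[nz, ] <- sums[nz, , drop = FALSE] / counts[nz]
    for (j in which(!nz)) {
      fd <- vapply(stats_list, `[[`, 0, "far_dist")
      Cnew[j, ] <- stats_list[[which.max(fd)]]$far_point
    }
    list(C = Cnew)
  }
  res <- multishot_engine(cons, data_key, k, C_init, max_iter, update,
                          "multishot_lloyd")
  new_cluster_result(res$C, res$labels, res$inertia, res$iterations,
                     res$variant, k)
}

#' Multishot decentralized gradient-descent K-means
#'
#' Same communication pattern as [multishot_lloyd()], but each site
#' computes the gradient of the K-means objective with respect to each
#' centroid on its local members (`g_j = c_j - local mean`), the
#' aggregator averages gradients weighted by local member counts, and the
#' centroids take a step `C <- C - lr * g`. With `lr = 1` this reduces to
#' Lloyd's update. If the global inertia increases for 5 consecutive
#' iterations the learning rate is halved with a warning. Converges when
#' assignments stabilize or the step norm falls below `tol`.
#'
#' @inheritParams multishot_lloyd
#' @param lr learning rate in (0, 1].
#' @param tol step-size convergence threshold.
#' @return a `cluster_result`.
#' @export
multishot_gradient <- function(cons, data_key, k, C_init, lr = 0.5,
                               max_iter = 300, tol = 1e-8) {
  if (lr <= 0) stop("learning rate must be positive")
  env <- new.env()
  env$lr <- lr
  env$bad <- 0L
  env$last_inertia <- Inf
  update <- function(C, stats_list) {
    counts <- Reduce(`+`, lapply(stats_list, `[[`, "counts"))
    sums <- Reduce(`+`, lapply(stats_list, `[[`, "sums"))
    G <- matrix(0, nrow(C), ncol(C))
    nz <- counts > 0
    G[nz, ] <- C[nz, , drop = FALSE] - sums[nz, , drop = FALSE] / counts[nz]
    inert <- sum(vapply(stats_list, `[[`, 0, "inertia"))
    # genuine divergence only: ignore fixed-point-level fluctuations
    if (inert > env$last_inertia + 1e-6 * max(1, abs(env$last_inertia))) {
      env$bad <- env$bad + 1L
      if (env$bad >= 5L) {
        env$lr <- env$lr / 2
        env$bad <- 0L
        warning("gradient K-means diverging; halving learning rate to ",
                env$lr)
      }
    } else {
      env$bad <- 0L
    }
    env$last_inertia <- inert
    step <- env$lr * G
    list(C = C - step, stop = max(abs(step)) < tol)
  }
  res <- multishot_engine(cons, data_key, k, C_init, max_iter, update,
                          "multishot_gradient", stop_on_stable_labels = FALSE)
  new_cluster_result(res$C, res$labels, res$inertia, res$iterations,
                     res$variant, k, extra = list(lr_final = env$lr))
}

## Deterministic farthest-first init: seeded first pick, then greedily the
## row maximizing the minimum correlation distance to already-chosen rows.
farthest_first_init <- function(X, k, seed) {
  n <- nrow(X)
  first <- with_seed(seed, sample.int(n, 1))
  chosen <- first
  if (k > 1) {
    D <- cor_dist(X, X)
    for (j in 2:k) {
      dmin <- apply(D[, chosen, drop = FALSE], 1, min)
      dmin[chosen] <- -Inf
      chosen <- c(chosen, which.max(dmin))
    }
  }
  X[chosen, , drop = FALSE]
}

#' Single-shot decentralized K-means (nearest-centroid merge)
#'
#' Each site runs local Lloyd's K-means to convergence (farthest-first
#' seeded initialization) and sends its k local centroids and member
#' counts to the aggregator, which runs count-weighted Lloyd's K-means on
#' the pooled `s * k` local centroids to merge them into k global
#' centroids. Sites then label their windows locally. A site with fewer
#' than k windows contributes one centroid per window, with a warning.
#'
#' @inheritParams multishot_lloyd
#' @param seed integer seed for the local and merge initializations.
#' @return a `cluster_result` with extra field `local_centroids`.
#' @export
singleshot_merge <- function(cons, data_key, k, seed = 1, max_iter = 100) {
  s <- length(cons$sites)
  agg <- cons$aggregator
  Xs <- lapply(seq_len(s), function(i) site_data(cons, i, data_key))
  locals <- vector("list", s)
  for (i in seq_len(s)) {
    X <- Xs[[i]]
    ki <- min(k, nrow(X))
    if (ki < k) warning("site ", i, " has only ", nrow(X),
                        " windows; contributing ", ki, " local centroids")
    fit <- pooled_lloyd(X, ki, farthest_first_init(X, ki, seed + i),
                        max_iter = max_iter)
    counts <- tabulate(fit$labels, nbins = ki)
    keep <- counts > 0
    locals[[i]] <- list(C = fit$C[keep, , drop = FALSE], counts = counts[keep])
    if (i != agg) {
      send(cons, "centroids", locals[[i]]$C, i, agg)
      send(cons, "counts", locals[[i]]$counts, i, agg)
    }
  }
  Call <- do.call(rbind, lapply(locals, `[[`, "C"))
  wall <- unlist(lapply(locals, `[[`, "counts"))
  ## count-weighted Lloyd's on the local centroids
  C <- farthest_first_init(Call, k, seed)
  labels_prev <- rep(0L, nrow(Call))
  for (it in seq_len(max_iter)) {
    lab <- assign_nearest(Call, C)
    Cnew <- C
    for (j in seq_len(k)) {
      mem <- lab == j
      if (any(mem)) {
        Cnew[j, ] <- colSums(Call[mem, , drop = FALSE] * wall[mem]) / sum(wall[mem])
      }
    }
    if (identical(lab, labels_prev)) break
    labels_prev <- lab
    C <- Cnew
  }
  for (i in setdiff(seq_len(s), agg)) send(cons, "centroids", C, agg, i)
  labels <- lapply(Xs, assign_nearest, C = C)
  inertia <- sum(vapply(seq_len(s), function(i) {
    D <- cor_dist(Xs[[i]], C)
    sum(D[cbind(seq_len(nrow(Xs[[i]])), labels[[i]])])
  }, 0))
  new_cluster_result(C, labels, inertia, NA_integer_, "singleshot_merge", k,
                     extra = list(local_centroids = locals))
}

#' Mean silhouette under correlation distance
#'
#' Standard silhouette width averaged over points, with silhouette 0 for
#' singleton clusters; `NA` when fewer than two clusters are present.
#'
#' @param X data matrix (points x features).
#' @param labels integer cluster labels.
#' @return mean silhouette width, or `NA`.
#' @export
silhouette_cor <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- sort(unique(labels))
  if (length(ks) < 2 || n < 3) return(NA_real_)
  D <- cor_dist(X, X)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) {
      sil[i] <- 0
      next
    }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(ks, labels[i]), function(kk) {
      mean(D[i, labels == kk])
    }, 0))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

## Decentralized run selection score: per-site silhouettes on local
## exemplars, count-weighted at the aggregator; sites without two local
## clusters abstain.
weighted_silhouette <- function(cons, Xs, labels) {
  vals <- vapply(seq_along(Xs), function(i) silhouette_cor(Xs[[i]], labels[[i]]),
                 0)
  wts <- vapply(Xs, nrow, 0L)
  ok <- !is.na(vals)
  agg <- cons$aggregator
  for (i in setdiff(seq_along(Xs), agg)) {
    send(cons, "scalar_stats", c(vals[i], wts[i]), i, agg)
  }
  if (!any(ok)) return(NA_real_)
  sum(vals[ok] * wts[ok]) / sum(wts[ok])
}

#' Two-stage decentralized state clustering
#'
#' Stage 1 clusters the exemplar windows: `n_init` runs, each initialized
#' by drawing k exemplar windows uniformly at random across sites (the
#' drawn rows are shared as centroids, which the protocol already permits),
#' scored by the count-weighted mean of per-site silhouettes; the winning
#' run's centroids become `C_0`. Stage 2 clusters all windows initialized
#' at `C_0`. Field defaults: `k = 5`, `n_init = 200` (tests use 20).
#'
#' @param cons a `consortium` after [compute_windows()].
#' @param k number of connectivity states.
#' @param n_init number of stage-1 initializations.
#' @param seed integer seed.
#' @param variant `"lloyd"` (default), `"gradient"`, or `"singleshot"`.
#' @param lr learning rate for the gradient variant.
#' @param max_iter iteration cap per K-means run.
#' @return a `cluster_result` for stage 2 with extra fields `C0`,
#'   `stage1_scores`, `best_run`, and `assignments` (data.frame site /
#'   subject / window / state).
#' @export
two_stage_clustering <- function(cons, k, n_init = 200, seed = 1,
                                 variant = c("lloyd", "gradient", "singleshot"),
                                 lr = 0.5, max_iter = 100) {
  variant <- match.arg(variant)
  s <- length(cons$sites)
  agg <- cons$aggregator
  Xex <- lapply(seq_len(s), function(i) site_data(cons, i, "exemplars"))
  counts <- vapply(Xex, nrow, 0L)
  for (i in setdiff(seq_len(s), agg)) send(cons, "counts", counts[i], i, agg)
  n_ex <- sum(counts)
  if (n_ex < k) stop("fewer exemplar windows than clusters")
  site_of <- rep(seq_len(s), counts)
  row_of <- unlist(lapply(counts, seq_len))
  run_one <- function(C_init) {
    switch(variant,
           lloyd = multishot_lloyd(cons, "exemplars", k, C_init, max_iter),
           gradient = multishot_gradient(cons, "exemplars", k, C_init,
                                         lr = lr, max_iter = max_iter),
           singleshot = singleshot_merge(cons, "exemplars", k, seed = seed,
                                         max_iter = max_iter))
  }
  scores <- numeric(n_init)
  best <- NULL
  for (run in seq_len(n_init)) {
    draw <- with_seed(seed + run, sample.int(n_ex, k))
    C_init <- do.call(rbind, lapply(draw, function(g) {
      row <- Xex[[site_of[g]]][row_of[g], ]
      if (site_of[g] != agg) {
        send(cons, "centroids", matrix(row, 1), site_of[g], agg)
      }
      row
    }))
    fit <- run_one(C_init)
    scores[run] <- weighted_silhouette(cons, Xex, fit$labels)
    if (is.null(best) || (!is.na(scores[run]) && scores[run] > best$score)) {
      best <- list(score = scores[run], fit = fit, run = run)
    }
  }
  C0 <- best$fit$C
  final <- switch(variant,
                  lloyd = multishot_lloyd(cons, "windows", k, C0, max_iter),
                  gradient = multishot_gradient(cons, "windows", k, C0,
                                                lr = lr, max_iter = max_iter),
                  singleshot = singleshot_merge(cons, "windows", k,
                                                seed = seed,
                                                max_iter = max_iter))
  idx <- do.call(rbind, lapply(seq_len(s), function(i) {
    site_data(cons, i, "window_index")
  }))
  idx$state <- unlist(final$labels)
  final$C0 <- C0
  final$stage1_scores <- scores
  final$best_run <- best$run
  final$assignments <- idx
  final
}
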