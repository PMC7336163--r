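# Shared fixtures and independent oracles, all built in code.

# All permutations of 1..n (n <= 7), for brute-force assignment oracles.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Brute-force linear assignment: column index per row minimizing total cost.
brute_assignment <- function(cost) {
  best <- NULL
  best_val <- Inf
  for (p in all_perms(nrow(cost))) {
    val <- sum(cost[cbind(seq_len(nrow(cost)), p)])
    if (val < best_val) {
      best_val <- val
      best <- p
    }
  }
  list(perm = best, cost = best_val)
}

# Exactly rank-r d x n matrix (no noise): decentralized PCA merges it
# without any en-route truncation, so pooled equivalence is exact.
make_lowrank <- function(d, n, r, seed, noise = 0) {
  X <- gen_gaussian(d, r, seed) %*% gen_gaussian(r, n, seed + 1000)
  if (noise > 0) X <- X + noise * gen_gaussian(d, n, seed + 2000)
  X
}

# Split columns of X into n_sites one-subject sites.
block_consortium <- function(X, n_sites, seed = 1) {
  nc <- ncol(X)
  sz <- rep(nc %/% n_sites, n_sites)
  sz[seq_len(nc %% n_sites)] <- sz[seq_len(nc %% n_sites)] + 1L
  idx <- split(seq_len(nc), rep(seq_len(n_sites), sz))
  build_consortium(rep(1L, n_sites), seed = seed,
                   subjects = lapply(idx, function(j) X[, j, drop = FALSE]))
}

# Consortium with per-site window/exemplar matrices computed from the
# planted timecourses (ICA bypassed via least squares on the true maps),
# for clustering tests that are not about ICA.
windows_consortium <- function(gs, site_counts, t = 22, seed = 1) {
  cons <- build_consortium(site_counts, seed = seed, subjects = gs$subjects)
  Ainv <- solve(crossprod(gs$truth$A), t(gs$truth$A))
  for (i in seq_along(cons$sites)) {
    st <- ddfnc:::site_store(cons, i)
    stacks <- lapply(cons$sites[[i]]$subjects, function(X) {
      sliding_window_corr(Ainv %*% X, t = t)
    })
    ex_idx <- lapply(stacks, select_exemplars)
    st$window_stacks <- stacks
    st$exemplar_idx <- ex_idx
    st$windows <- do.call(rbind, stacks)
    st$exemplars <- do.call(rbind, Map(function(V, ix) V[ix, , drop = FALSE],
                                       stacks, ex_idx))
    st$window_index <- do.call(rbind, Map(
      function(nm, V) data.frame(site = i, subject = nm,
                                 window = seq_len(nrow(V))),
      names(stacks), stacks))
  }
  cons
}

# Best-permutation label agreement (confusion matrix + Hungarian),
# the "adjusted agreement" used for planted-state recovery.
label_agreement <- function(est, truth, k) {
  conf <- table(factor(est, levels = seq_len(k)),
                factor(truth, levels = seq_len(k)))
  sol <- clue::solve_LSAP(max(conf) - conf)
  sum(conf[cbind(seq_len(k), as.integer(sol))]) / length(est)
}

expect_subspace_equal <- function(A, B, tol = 1e-6) {
  expect_lt(max(principal_angles(A, B)), tol)
}

principal_angles <- ddfnc:::principal_angles
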