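test_that("correlation_distance hits its closed-form values", {
  u <- c(1, 3, 2, 5)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u), 2)
  expect_error(correlation_distance(u, rep(1, 4)), "zero-variance")
  expect_error(correlation_distance(u, u[1:3]), "length")
  expect_error(correlation_distance(1:2, 2:1), ">= 3")
})

# Small planted-state clustering fixture reused across tests. Windows of
# 31 samples over well-separated states (min centroid distance 0.8) and
# dwell 70 >> window keep the state-assignment problem identifiable at
# this scale; shorter windows make even the planted-centroid oracle miss.
cluster_fixture <- function(seed, n_subjects = 6, site_counts = c(3, 3),
                            k_states = 3) {
  gs <- gen_state_dataset(d = 120, n_subjects = n_subjects, n_time = 140,
                          r = 5, k_states = k_states, dwell = 70,
                          noise_sd = 0, seed = seed, min_sep = 0.8)
  list(gs = gs, cons = windows_consortium(gs, site_counts, t = 30,
                                          seed = seed))
}

test_that("multishot Lloyd's is label-identical to pooled Lloyd's", {
  for (seed in 61:65) {
    fx <- cluster_fixture(seed)
    Xall <- gather_windows(fx$cons)
    C0 <- ddfnc:::farthest_first_init(Xall, 3, seed)
    dec <- multishot_lloyd(fx$cons, "windows", 3, C0)
    pool <- pooled_lloyd(Xall, 3, C0)
    expect_identical(unlist(dec$labels, use.names = FALSE), pool$labels)
    expect_equal(dec$C, pool$C)
    expect_equal(dec$inertia, pool$inertia)
  }
})

test_that("single-site multishot Lloyd's equals the pooled trajectory", {
  fx <- cluster_fixture(70, n_subjects = 4, site_counts = 4)
  Xall <- gather_windows(fx$cons)
  C0 <- Xall[c(1, 50, 100), ]
  dec <- multishot_lloyd(fx$cons, "windows", 3, C0)
  pool <- pooled_lloyd(Xall, 3, C0)
  expect_identical(unlist(dec$labels, use.names = FALSE), pool$labels)
  expect_identical(dec$iterations, pool$iterations)
})

test_that("Lloyd's inertia never increases and centroids are weighted means", {
  fx <- cluster_fixture(71)
  Xall <- gather_windows(fx$cons)
  C0 <- ddfnc:::farthest_first_init(Xall, 3, 71)
  dec <- multishot_lloyd(fx$cons, "windows", 3, C0)
  # the mean update is not the exact correlation-distance minimizer, so
  # monotonicity holds only up to a small slack near convergence
  expect_true(all(diff(dec$inertia) <= 1e-3 * dec$inertia[1]))
  expect_lt(utils::tail(dec$inertia, 1), dec$inertia[1])
  # final global centroid j = count-weighted mean of members across sites
  lab <- unlist(dec$labels, use.names = FALSE)
  for (j in 1:3) {
    expect_equal(dec$C[j, ], colMeans(Xall[lab == j, , drop = FALSE]))
  }
})

test_that("empty clusters are re-seeded from the farthest point", {
  fx <- cluster_fixture(72)
  Xall <- gather_windows(fx$cons)
  # duplicate initial centroids guarantee an initially empty cluster
  C0 <- Xall[c(1, 1, 1), ] + 0
  dec <- multishot_lloyd(fx$cons, "windows", 3, C0)
  expect_setequal(unique(unlist(dec$labels)), 1:3)
  pool <- pooled_lloyd(Xall, 3, C0)
  expect_identical(unlist(dec$labels, use.names = FALSE), pool$labels)
})

test_that("the aggregated gradient equals the analytic pooled gradient", {
  fx <- cluster_fixture(73)
  Xall <- gather_windows(fx$cons)
  C0 <- ddfnc:::farthest_first_init(Xall, 3, 73)
  lr <- 0.3
  dec <- multishot_gradient(fx$cons, "windows", 3, C0, lr = lr, max_iter = 1)
  # oracle: one explicit gradient step on pooled data
  lab <- ddfnc:::assign_nearest(Xall, C0)
  C1 <- C0
  for (j in 1:3) {
    mem <- lab == j
    if (any(mem)) {
      g <- C0[j, ] - colMeans(Xall[mem, , drop = FALSE])
      C1[j, ] <- C0[j, ] - lr * g
    }
  }
  expect_equal(dec$C, C1)
})

test_that("gradient descent with exact-assignment init converges to the points", {
  set.seed(74)
  pts <- ddfnc:::row_standardize(matrix(rnorm(9), 3, 3) %*%
                                   matrix(rnorm(18), 3, 6))
  cons <- build_consortium(1, seed = 1, subjects = list(matrix(rnorm(8), 4, 2)))
  st <- ddfnc:::site_store(cons, 1)
  st$pts <- pts
  fit <- multishot_gradient(cons, "pts", 3, pts + 0.01, lr = 0.5,
                            max_iter = 200)
  expect_equal(fit$C, unname(pts), tolerance = 1e-4)
})

test_that("gradient K-means tracks pooled Lloyd's on planted states", {
  fx <- cluster_fixture(75)
  Xall <- gather_windows(fx$cons)
  C0 <- ddfnc:::farthest_first_init(Xall, 3, 75)
  pool <- pooled_lloyd(Xall, 3, C0)
  grad <- suppressWarnings(multishot_gradient(fx$cons, "windows", 3, C0,
                                              lr = 0.5, max_iter = 300))
  expect_gt(hungarian_match(t(grad$C), t(pool$C))$min, 0.85)
})

test_that("single-shot merging handles replicated and well-separated data", {
  # identical data on both sites: merged centroids equal the local ones
  gs <- gen_state_dataset(d = 100, n_subjects = 1, n_time = 90, r = 5,
                          k_states = 3, dwell = 30, noise_sd = 0, seed = 76)
  gs2 <- gs
  gs2$subjects <- rep(gs$subjects, 2)
  gs2$truth$S <- rep(gs$truth$S, 2)
  gs2$truth$state_sequences <- rep(gs$truth$state_sequences, 2)
  cons <- windows_consortium(gs2, c(1, 1), t = 15, seed = 76)
  fit <- singleshot_merge(cons, "windows", 3, seed = 5)
  local_fit <- pooled_lloyd(ddfnc:::site_data(cons, 1, "windows"), 3,
                            ddfnc:::farthest_first_init(
                              ddfnc:::site_data(cons, 1, "windows"), 3, 6))
  # local runs use different seeded inits, so allow tiny optimizer drift
  m <- hungarian_match(t(fit$C), t(local_fit$C))
  expect_gt(m$min, 0.99)
  # single site: reduces to local K-means labels
  cons1 <- windows_consortium(gs, 1, t = 15, seed = 77)
  fit1 <- singleshot_merge(cons1, "windows", 3, seed = 7)
  expect_setequal(unique(unlist(fit1$labels)), 1:3)
})

test_that("single-shot merging exactly recovers well-separated planted clusters", {
  # blobs around near-orthogonal directions, between/within ratio >= 10
  set.seed(78)
  centers <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
  pts <- do.call(rbind, lapply(1:3, function(j) {
    matrix(rep(centers[, j], 20), 20, byrow = TRUE) +
      matrix(rnorm(20 * 100, sd = 0.02), 20)
  }))
  truth_lab <- rep(1:3, each = 20)
  ord <- sample(60)
  cons <- build_consortium(c(1, 1), seed = 8,
                           subjects = replicate(2, matrix(rnorm(8), 4, 2),
                                                simplify = FALSE))
  for (i in 1:2) {
    st <- ddfnc:::site_store(cons, i)
    st$windows <- pts[ord[(30 * (i - 1) + 1):(30 * i)], ]
  }
  fit <- singleshot_merge(cons, "windows", 3, seed = 9)
  est <- unlist(fit$labels)
  expect_equal(label_agreement(est, truth_lab[ord], 3), 1)
})

test_that("two-stage clustering is deterministic and recovers planted states", {
  fx <- cluster_fixture(80, n_subjects = 8, site_counts = c(4, 4),
                        k_states = 3)
  fitA <- two_stage_clustering(fx$cons, k = 3, n_init = 5, seed = 2)
  fitB <- two_stage_clustering(fx$cons, k = 3, n_init = 5, seed = 2)
  expect_identical(fitA$C, fitB$C)
  expect_identical(fitA$labels, fitB$labels)
  expect_identical(fitA$best_run, fitB$best_run)
  # n_init = 1 is fully deterministic end-to-end as the degenerate case
  fit1 <- two_stage_clustering(fx$cons, k = 3, n_init = 1, seed = 3)
  expect_identical(fit1$C, two_stage_clustering(fx$cons, k = 3, n_init = 1,
                                                seed = 3)$C)
  # planted-state recovery with adjusted label agreement > 0.9
  tl <- unlist(true_window_labels(fx$gs$truth, 30))
  agree <- label_agreement(unlist(fitA$labels), tl, 3)
  expect_gt(agree, 0.9)
  expect_identical(nrow(fitA$assignments), length(tl))
})

test_that("stage-two initialization from exemplar centroids matches pooled", {
  fx <- cluster_fixture(81)
  fit <- two_stage_clustering(fx$cons, k = 3, n_init = 5, seed = 4)
  pool <- pooled_lloyd(gather_windows(fx$cons), 3, fit$C0)
  expect_identical(unlist(fit$labels, use.names = FALSE), pool$labels)
  expect_gt(hungarian_match(t(fit$C), t(pool$C))$min, 0.999)
})

test_that("weighted silhouette matches a manual small-case computation", {
  X1 <- rbind(c(1, 2, 3, 1), c(1.1, 2, 3, 1), c(3, 1, -2, 0))
  X2 <- rbind(c(3.2, 1, -2, 0), c(2.9, 1.2, -2, 0.1))
  lab1 <- c(1L, 1L, 2L)
  lab2 <- c(2L, 2L)
  s1 <- silhouette_cor(X1, lab1)
  expect_true(is.finite(s1))
  expect_true(is.na(silhouette_cor(X2, lab2)))  # one cluster locally
  cons <- build_consortium(c(1, 1), seed = 1,
                           subjects = replicate(2, matrix(rnorm(8), 4, 2),
                                                simplify = FALSE))
  got <- ddfnc:::weighted_silhouette(cons, list(X1, X2), list(lab1, lab2))
  expect_equal(got, s1)  # site 2 abstains, so the weighted mean is site 1's
})
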