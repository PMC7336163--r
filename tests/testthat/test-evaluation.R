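test_that("amari_isi hits its closed-form values and invariances", {
  expect_equal(amari_isi(diag(4)), 0)
  # signed, scaled permutation: still exactly zero
  P <- diag(c(3, -0.5, 7, 1))[, c(2, 4, 1, 3)]
  expect_equal(amari_isi(P), 0)
  # all-ones: every row and column contributes r - 1, normalization cancels
  expect_equal(amari_isi(matrix(1, 5, 5)), 1)
  expect_error(amari_isi(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_error(amari_isi(matrix(1, 2, 3)), "square")
  # invariant to permutation and global scaling; scaled permutations stay 0
  # (per-row or per-column rescaling of a *general* matrix does change the
  # index: only the row term normalizes per row, only the column term per
  # column)
  set.seed(1)
  M <- matrix(rnorm(36), 6, 6)
  base <- amari_isi(M)
  expect_gte(base, 0)
  expect_lte(base, 1)
  expect_equal(amari_isi(3.7 * M), base)
  expect_equal(amari_isi(M[sample(6), sample(6)]), base)
  D1 <- diag(runif(6, 0.5, 2) * sample(c(-1, 1), 6, TRUE))
  D2 <- diag(runif(6, 0.5, 2) * sample(c(-1, 1), 6, TRUE))
  P <- diag(6)[, sample(6)]
  expect_equal(amari_isi(D1 %*% P %*% D2), 0)
})

test_that("hungarian_match recovers permutations and beats identity cost", {
  ref <- gen_gaussian(50, 4, seed = 2)
  m_self <- hungarian_match(ref, ref)
  expect_identical(m_self$permutation, 1:4)
  expect_equal(m_self$correlations, rep(1, 4))
  perm <- c(3L, 1L, 4L, 2L)
  m_perm <- hungarian_match(ref[, perm], ref)
  expect_identical(perm[m_perm$permutation], 1:4)
  # sign flips are reconciled after matching
  m_sign <- hungarian_match(-ref, ref)
  expect_equal(m_sign$correlations, rep(1, 4))
  expect_equal(m_sign$est_aligned, ref)
  # optimality lower bound
  est <- gen_gaussian(50, 4, seed = 3)
  m <- hungarian_match(est, ref)
  R <- abs(cor(ref, est))
  expect_lte(sum(1 - m$correlations), sum(1 - diag(R)) + 1e-12)
})

test_that("hungarian assignment equals brute force for small problems", {
  for (r in 3:6) {
    for (seed in 1:3) {
      est <- gen_gaussian(30, r, seed = seed * 100 + r)
      ref <- gen_gaussian(30, r, seed = seed * 100 + r + 50)
      m <- hungarian_match(est, ref)
      cost <- pmax(1 - abs(cor(ref, est)), 0)
      bf <- brute_assignment(cost)
      expect_equal(sum(1 - abs(m$correlations)), bf$cost, tolerance = 1e-10)
    }
  }
})

test_that("rectangular matching assigns on the smaller side", {
  A <- gen_gaussian(40, 6, seed = 4)
  ref <- A[, c(5, 2)]
  m <- hungarian_match(A, ref)
  expect_identical(m$pairs$est, c(5L, 2L))
  expect_identical(match_reference_components(A, ref), c(5L, 2L))
  # swapped orientation: more references than estimates
  m2 <- hungarian_match(A[, 1:2], A)
  expect_identical(nrow(m2$pairs), 2L)
})

test_that("reference-guided selection survives noise within reason", {
  A <- gen_gaussian(300, 6, seed = 5)
  idx <- c(1L, 4L, 6L)
  ref <- A[, idx] + 0.2 * gen_gaussian(300, 3, seed = 6)
  expect_identical(sort(match_reference_components(A, ref)), idx)
})

test_that("group_state_contrast is null on identical groups and detects a planted shift", {
  # construct assignments and windows directly: 2 states, 12 subjects
  p <- 6
  n_sub <- 12
  subj <- sprintf("s%02d", seq_len(n_sub))
  set.seed(7)
  rows <- list()
  win <- list()
  for (i in seq_len(n_sub)) {
    for (st in 1:2) {
      nw <- 16
      rows[[length(rows) + 1]] <- data.frame(site = 1L, subject = subj[i],
                                             window = seq_len(nw), state = st)
      win[[length(win) + 1]] <- matrix(rnorm(nw * p, mean = st), nw, p)
    }
  }
  asn <- do.call(rbind, rows)
  W <- do.call(rbind, win)
  res <- list(assignments = asn, k = 2L)
  groups_same <- setNames(rep(c("A", "B"), each = 6), subj)
  con0 <- group_state_contrast(res, W, groups_same)
  # same generating distribution: t values are small and centered on zero
  expect_lt(max(abs(con0$t_matrices[[1]])), 6)
  expect_identical(dim(con0$t_matrices[[1]]), c(4L, 4L))
  expect_equal(diag(con0$t_matrices[[1]]), rep(0, 4))
  # plant a +1 sd shift in state 2, element 3, group B only
  W2 <- W
  b_rows <- asn$subject %in% subj[7:12] & asn$state == 2
  W2[b_rows, 3] <- W2[b_rows, 3] + 1
  con1 <- group_state_contrast(res, W2, groups_same)
  t2 <- con1$t_matrices[[2]]
  planted <- abs(vec_upper(t2)[3])
  expect_gt(planted, 4)
  expect_gt(planted, max(abs(vec_upper(t2)[-3])))
  # t matches the closed-form pooled two-sample oracle on the medians
  med_a <- con1$medians[[2]][["A"]][, 3]
  med_b <- con1$medians[[2]][["B"]][, 3]
  tt <- t.test(med_a, med_b, var.equal = TRUE)
  expect_equal(vec_upper(t2)[3], unname(tt$statistic), tolerance = 1e-10)
  # Welch flag changes the standard error
  conw <- group_state_contrast(res, W2, groups_same, welch = TRUE)
  ttw <- t.test(med_a, med_b)
  expect_equal(vec_upper(conw$t_matrices[[2]])[3], unname(ttw$statistic),
               tolerance = 1e-10)
})

test_that("contrast flags states without enough subjects per group", {
  asn <- data.frame(site = 1L,
                    subject = rep(c("a", "b", "c", "d"), each = 2),
                    window = rep(1:2, 4),
                    state = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L))
  W <- matrix(rnorm(8 * 6), 8, 6)
  groups <- setNames(c("A", "A", "B", "B"), c("a", "b", "c", "d"))
  con <- group_state_contrast(list(assignments = asn, k = 2L), W, groups)
  expect_identical(con$missing_states, 2L)
  expect_null(con$t_matrices[[2]])
  expect_false(is.null(con$t_matrices[[1]]))
})

test_that("permuted group labels give nominal type-I error", {
  # permutation-null sanity check at alpha = 0.05, 500 reps
  set.seed(8)
  n <- 10
  med_a <- matrix(rnorm(n * 3), n, 3)
  med_b <- matrix(rnorm(n * 3), n, 3)
  all_m <- rbind(med_a, med_b)
  crit <- qt(0.975, df = 2 * n - 2)
  hits <- 0L
  reps <- 500
  for (i in seq_len(reps)) {
    idx <- sample(2 * n, n)
    tv <- ddfnc:::two_sample_t(all_m[idx, , drop = FALSE],
                               all_m[-idx, , drop = FALSE])
    hits <- hits + (abs(tv[1]) > crit)
  }
  rate <- hits / reps
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("planted centroids can be realigned into estimated coordinates", {
  gs <- gen_state_dataset(d = 200, n_subjects = 2, n_time = 60, r = 4,
                          k_states = 2, seed = 9)
  # fake estimate: permuted, sign-flipped, noisy copy of the truth
  perm <- c(3, 1, 4, 2)
  sgn <- c(1, -1, 1, -1)
  A_hat <- sweep(gs$truth$A[, perm], 2, sgn, "*") +
    0.01 * gen_gaussian(200, 4, seed = 10)
  re <- realign_planted_centroids(gs$truth, A_hat)
  # oracle: apply the known permutation/sign by hand
  for (s in 1:2) {
    C <- gs$truth$state_centroids[[s]]
    manual <- C[perm, perm] * tcrossprod(sgn)
    diag(manual) <- 1
    expect_equal(re$centroids[[s]], manual, tolerance = 1e-12)
  }
})
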