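## Quality metrics and group statistics: the Moreau-Amari index for source
## separation agreement, Hungarian matching of components and centroids by
## correlation, reference-guided component selection, and two-sample
## contrasts on per-state subject medians.

#' Moreau-Amari inter-symbol interference index
#'
#' Permutation- and scale-invariant measure in `[0, 1]` of how far a
#' square matrix is from a scaled permutation:
#' \deqn{ISI(P) = \frac{\sum_i (\sum_j |p_{ij}| / \max_j |p_{ij}| - 1) +
#'   \sum_j (\sum_i |p_{ij}| / \max_i |p_{ij}| - 1)}{2 r (r - 1)}}
#' Zero iff `P` is a signed, scaled permutation; 1 for the all-ones
#' matrix. `P` is typically the product of an estimated unmixing matrix
#' and a reference mixing matrix.
#'
#' @param P r x r matrix with no all-zero row or column.
#' @return scalar in `[0, 1]`.
#' @examples
#' amari_isi(diag(4))            # 0
#' amari_isi(matrix(1, 4, 4))    # 1
#' @export
amari_isi <- function(P) {
  P <- abs(as.matrix(P))
  r <- nrow(P)
  if (ncol(P) != r || r < 2) stop("P must be square with r >= 2")
  rmax <- apply(P, 1, max)
  cmax <- apply(P, 2, max)
  if (any(rmax == 0) || any(cmax == 0)) {
    stop("all-zero row or column: ISI undefined")
  }
  (sum(rowSums(P) / rmax - 1) + sum(colSums(P) / cmax - 1)) / (2 * r * (r - 1))
}

#' Hungarian matching of components by correlation
#'
#' Finds the assignment between the columns of `est` and `ref` minimizing
#' total cost `1 - |Pearson correlation|` (solved with the Hungarian
#' algorithm; rectangular problems are assigned on the smaller side).
#' Matched `est` columns are sign-flipped so their matched correlations
#' are positive.
#'
#' @param est estimated components, d x r_e.
#' @param ref reference components, d x r_r (same d).
#' @return a `match_report`: list with `pairs` (data.frame `ref`, `est`,
#'   `correlation`), `permutation` (est column index per ref column, when
#'   `r_e >= r_r`), `correlations`, `min`, `mean`, and `est_aligned` (the
#'   matched, sign-corrected est columns in ref order).
#' @export
hungarian_match <- function(est, ref) {
  est <- as.matrix(est)
  ref <- as.matrix(ref)
  if (nrow(est) != nrow(ref)) stop("est and ref must share the row dimension")
  ## R[j, i] = cor(ref_j, est_i)
  R <- tcrossprod(row_standardize(t(ref)), row_standardize(t(est)))
  if (any(!is.finite(R))) stop("zero-variance column in matching")
  swapped <- ncol(est) < ncol(ref)
  cost <- pmax(1 - abs(if (swapped) t(R) else R), 0)
  sol <- clue::solve_LSAP(cost)
  if (swapped) {
    est_idx <- seq_len(ncol(est))
    ref_idx <- as.integer(sol)
  } else {
    ref_idx <- seq_len(ncol(ref))
    est_idx <- as.integer(sol)
  }
  cors <- R[cbind(ref_idx, est_idx)]
  sgn <- ifelse(cors < 0, -1, 1)
  ord <- order(ref_idx)
  ref_idx <- ref_idx[ord]
  est_idx <- est_idx[ord]
  cors <- (cors * sgn)[ord]
  aligned <- sweep(est[, est_idx, drop = FALSE], 2, sgn[ord], "*")
  structure(
    list(pairs = data.frame(ref = ref_idx, est = est_idx, correlation = cors),
         permutation = if (!swapped) est_idx else NULL,
         signs = sgn[ord], correlations = cors,
         min = min(cors), mean = mean(cors), est_aligned = aligned),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report:", nrow(x$pairs), "matched pairs; |cor| min",
      signif(x$min, 4), "mean", signif(x$mean, 4), "\n")
  invisible(x)
}

#' Select estimated components best matching a reference set
#'
#' Hungarian-matches the estimated components to `ref` and returns the
#' indices of the matched subset, mimicking reference-guided selection of
#' neurologically meaningful components from a larger decomposition.
#'
#' @param A_hat estimated components, d x r.
#' @param ref reference components, d x m with `m <= r`.
#' @return integer vector of length m: for each reference column, the
#'   matching column index of `A_hat`.
#' @export
match_reference_components <- function(A_hat, ref) {
  if (ncol(ref) > ncol(A_hat)) stop("reference set larger than estimate set")
  hungarian_match(A_hat, ref)$permutation
}

## Element-wise pooled-variance (or Welch) two-sample t on two stacks of
## vectorized matrices (subjects x elements).
two_sample_t <- function(Ma, Mb, welch = FALSE) {
  na <- nrow(Ma)
  nb <- nrow(Mb)
  ma <- colMeans(Ma)
  mb <- colMeans(Mb)
  va <- apply(Ma, 2, stats::var)
  vb <- apply(Mb, 2, stats::var)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  (ma - mb) / se
}

#' Group contrast of per-state subject medians
#'
#' For each state, computes each subject's element-wise median over the
#' windows assigned to that state, then contrasts the two groups with an
#' element-wise two-sample t-test (pooled variance by default; Welch
#' behind a flag). No multiple-comparison correction is applied: the t
#' maps are raw, as is conventional for state-difference displays.
#'
#' @param result a `cluster_result` with an `assignments` data.frame
#'   (site, subject, window, state), e.g. from [two_stage_clustering()].
#' @param windows matrix of vectorized windowed correlations whose rows
#'   align with `result$assignments`.
#' @param groups named character vector mapping subject id to one of two
#'   group labels.
#' @param welch use Welch's t instead of pooled variance.
#' @return a `group_state_contrast`: list with per-state `t_matrices`
#'   (square, diagonal 0, `NULL` with a flag when a group has fewer than 2
#'   subjects in the state), `medians` (per state, per group: subjects x
#'   elements), `group_sizes`, and `missing_states`.
#' @export
group_state_contrast <- function(result, windows, groups, welch = FALSE) {
  asn <- result$assignments
  if (is.null(asn)) stop("cluster result carries no window assignments")
  windows <- as.matrix(windows)
  if (nrow(windows) != nrow(asn)) stop("windows rows must align with assignments")
  glev <- sort(unique(groups))
  if (length(glev) != 2) stop("need exactly two groups")
  k <- result$k
  t_matrices <- vector("list", k)
  medians <- vector("list", k)
  missing <- integer(0)
  for (st in seq_len(k)) {
    med_by_group <- lapply(glev, function(g) {
      subj <- names(groups)[groups == g]
      rows <- lapply(subj, function(sb) {
        sel <- asn$subject == sb & asn$state == st
        if (!any(sel)) return(NULL)
        apply(windows[sel, , drop = FALSE], 2, stats::median)
      })
      rows <- Filter(Negate(is.null), rows)
      if (!length(rows)) return(matrix(numeric(0), 0, ncol(windows)))
      do.call(rbind, rows)
    })
    names(med_by_group) <- glev
    medians[[st]] <- med_by_group
    if (any(vapply(med_by_group, nrow, 0L) < 2)) {
      missing <- c(missing, st)
      t_matrices[st] <- list(NULL)
    } else {
      tv <- two_sample_t(med_by_group[[1]], med_by_group[[2]], welch = welch)
      t_matrices[[st]] <- devec_upper(tv, diag = 0)
    }
  }
  structure(
    list(t_matrices = t_matrices, medians = medians,
         group_sizes = table(groups), missing_states = missing,
         groups = glev, welch = welch),
    class = "group_state_contrast"
  )
}

#' @export
print.group_state_contrast <- function(x, ...) {
  cat("group_state_contrast:", length(x$t_matrices), "states, groups",
      paste(x$groups, collapse = " vs "), "\n")
  if (length(x$missing_states)) {
    cat("  states without enough subjects:",
        paste(x$missing_states, collapse = " "), "\n")
  }
  invisible(x)
}

#' Express planted state centroids in estimated component coordinates
#'
#' ICA recovers spatial components only up to permutation and sign, so a
#' planted r x r connectivity centroid must be re-indexed before it can be
#' compared with centroids estimated from back-reconstructed timecourses.
#' This matches the estimated maps to the planted maps and returns each
#' planted centroid with rows/columns permuted into estimated-component
#' order and signs flipped accordingly
#' (`C'[e, f] = s_e s_f C[p(e), p(f)]`).
#'
#' @param truth a `ground_truth` from [gen_state_dataset()].
#' @param A_hat estimated spatial maps, d x r (same r as the truth).
#' @return list with `centroids` (list of realigned matrices), `vectors`
#'   (k_states x r(r-1)/2 matrix of their upper triangles), and `match`
#'   (the underlying `match_report`).
#' @export
realign_planted_centroids <- function(truth, A_hat) {
  if (ncol(A_hat) != truth$r) stop("component counts differ")
  m <- hungarian_match(A_hat, truth$A)
  true_of_est <- integer(truth$r)
  sign_of_est <- numeric(truth$r)
  true_of_est[m$pairs$est] <- m$pairs$ref
  sign_of_est[m$pairs$est] <- m$signs
  cents <- lapply(truth$state_centroids, function(C) {
    out <- C[true_of_est, true_of_est, drop = FALSE] *
      tcrossprod(sign_of_est)
    diag(out) <- 1
    out
  })
  list(centroids = cents,
       vectors = do.call(rbind, lapply(cents, vec_upper)),
       match = m)
}
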