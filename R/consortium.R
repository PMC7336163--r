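## In-process simulation of a decentralized consortium: sites hold private
## subject matrices, a message channel enforces a statistics-only whitelist
## and logs all traffic, and one site acts as the aggregator.

#' Message kinds allowed on the consortium channel
#'
#' Only derived statistics may cross the simulated network. There is no
#' message kind for raw subject data, so a privacy violation is
#' unrepresentable by construction; [send()] additionally refuses unknown
#' kinds at run time.
#'
#' @return character vector of permitted message kinds.
#' @export
message_whitelist <- function() {
  c("eigen_package", "unmixing_maps", "centroids", "gradients",
    "counts", "scalar_stats")
}

#' Build a simulated multi-site consortium
#'
#' Assigns subject matrices to sites in order (the first
#' `site_subject_counts[1]` subjects to site 1, and so on) and draws a
#' random site ordering `order` from the seed. The last site in that
#' ordering acts as the aggregator: it is where round-robin PCA terminates
#' and where ICA and centroid averaging run.
#'
#' @param site_subject_counts integer vector, subjects per site (all >= 1).
#' @param seed integer seed controlling the site ordering.
#' @param subjects optional list of voxels x timepoints matrices to
#'   distribute; must have length `sum(site_subject_counts)`. May be `NULL`
#'   to build an empty shell that is populated later.
#' @return an object of class `consortium`.
#' @examples
#' subs <- replicate(4, matrix(rnorm(50), 10, 5), simplify = FALSE)
#' cons <- build_consortium(c(2, 2), seed = 1, subjects = subs)
#' cons$order
#' @export
build_consortium <- function(site_subject_counts, seed = 1, subjects = NULL) {
  counts <- as.integer(site_subject_counts)
  if (length(counts) == 0) stop("empty consortium: no sites")
  if (any(counts < 1)) stop("every site needs at least one subject")
  s <- length(counts)
  n_sub <- sum(counts)
  if (!is.null(subjects)) {
    if (length(subjects) != n_sub) {
      stop("need ", n_sub, " subjects, got ", length(subjects))
    }
    d <- vapply(subjects, nrow, 0L)
    if (length(unique(d)) != 1) stop("subjects differ in voxel dimension")
  }
  ord <- with_seed(seed, sample.int(s))
  idx_end <- cumsum(counts)
  idx_start <- c(1L, utils::head(idx_end, -1) + 1L)
  sites <- vector("list", s)
  sub_id <- 0L
  for (i in seq_len(s)) {
    subs_i <- if (is.null(subjects)) list() else subjects[idx_start[i]:idx_end[i]]
    if (length(subs_i)) {
      names(subs_i) <- sprintf("subj_%03d", sub_id + seq_along(subs_i))
    }
    sub_id <- sub_id + counts[i]
    sites[[i]] <- list(index = i, subjects = subs_i, store = new.env(parent = emptyenv()))
  }
  channel <- new.env(parent = emptyenv())
  channel$log <- list()
  channel$step <- 0L
  structure(
    list(sites = sites, order = ord, aggregator = ord[s], seed = as.integer(seed),
         channel = channel),
    class = "consortium"
  )
}

#' @export
print.consortium <- function(x, ...) {
  cat("consortium:", length(x$sites), "sites,",
      sum(vapply(x$sites, function(s) length(s$subjects), 0L)), "subjects\n")
  cat("  order:", paste(x$order, collapse = " "),
      "| aggregator: site", x$aggregator, "\n")
  cat("  messages logged:", length(x$channel$log), "\n")
  invisible(x)
}

#' Send a statistics payload between sites
#'
#' The only way information crosses sites in this package. The payload is
#' copied (R value semantics), the kind is checked against
#' [message_whitelist()], and the transfer is appended to the traffic log.
#'
#' @param cons a `consortium`.
#' @param kind message kind; must be whitelisted.
#' @param payload numeric matrix or vector of derived statistics.
#' @param src,dst site indices.
#' @return invisibly, a delivery receipt (list with step and byte count).
#' @export
send <- function(cons, kind, payload, src, dst) {
  if (!kind %in% message_whitelist()) {
    stop("privacy violation: message kind '", kind,
         "' is not on the statistics whitelist", call. = FALSE)
  }
  if (!is.numeric(payload)) stop("payload must be numeric statistics")
  pm <- as.matrix(payload)
  ch <- cons$channel
  ch$step <- ch$step + 1L
  entry <- list(step = ch$step, kind = kind, src = as.integer(src),
                dst = as.integer(dst), rows = nrow(pm), cols = ncol(pm),
                bytes = 8L * nrow(pm) * ncol(pm), payload = pm)
  ch$log[[length(ch$log) + 1L]] <- entry
  invisible(list(step = entry$step, bytes = entry$bytes))
}

#' Traffic log of a consortium
#'
#' @param cons a `consortium`.
#' @return data.frame with one row per message: step, kind, src, dst, rows,
#'   cols, bytes. Payloads are retained internally for [audit_privacy()].
#' @export
traffic_log <- function(cons) {
  lg <- cons$channel$log
  if (!length(lg)) {
    return(data.frame(step = integer(), kind = character(), src = integer(),
                      dst = integer(), rows = integer(), cols = integer(),
                      bytes = integer()))
  }
  data.frame(
    step = vapply(lg, `[[`, 0L, "step"),
    kind = vapply(lg, `[[`, "", "kind"),
    src = vapply(lg, `[[`, 0L, "src"),
    dst = vapply(lg, `[[`, 0L, "dst"),
    rows = vapply(lg, `[[`, 0L, "rows"),
    cols = vapply(lg, `[[`, 0L, "cols"),
    bytes = vapply(lg, `[[`, 0L, "bytes")
  )
}

#' Clear the traffic log
#' @param cons a `consortium`.
#' @return the consortium, invisibly.
#' @export
reset_traffic <- function(cons) {
  cons$channel$log <- list()
  cons$channel$step <- 0L
  invisible(cons)
}

## Concatenated raw data of one site (voxels x total site timepoints),
## or a derived per-site matrix stored by a pipeline stage.
site_data <- function(cons, i, key = "data") {
  site <- cons$sites[[i]]
  if (key == "data") {
    if (is.null(site$store$data_cache)) {
      site$store$data_cache <- do.call(cbind, site$subjects)
    }
    return(site$store$data_cache)
  }
  val <- get0(key, envir = site$store, inherits = FALSE)
  if (is.null(val)) stop("site ", i, " has no stored '", key, "' matrix")
  val
}

site_store <- function(cons, i) cons$sites[[i]]$store

#' Audit the traffic log for privacy violations
#'
#' Checks two conditions over every logged payload: (a) no payload has more
#' columns than the largest legitimate statistics object
#' (`max_cols`, typically `max(k1, k2, r, k * n_features)`), and (b) no
#' payload column reproduces a raw subject column up to sign and scale
#' (|Pearson correlation| == 1 within tolerance). Columns are only compared
#' when the payload lives in voxel space (same row count as the data).
#'
#' @param cons a `consortium`.
#' @param max_cols integer cap on payload column counts.
#' @param check_raw compare payload columns against raw subject columns.
#' @param tol tolerance on |correlation| for the raw-column check.
#' @return list with `ok` (logical) and a data.frame of `violations`.
#' @export
audit_privacy <- function(cons, max_cols, check_raw = TRUE, tol = 1e-8) {
  lg <- cons$channel$log
  viol <- list()
  d <- NULL
  raw_std <- NULL
  if (check_raw) {
    raw <- do.call(cbind, unlist(lapply(cons$sites, `[[`, "subjects"),
                                 recursive = FALSE))
    if (!is.null(raw)) {
      d <- nrow(raw)
      raw_std <- row_standardize(t(raw), zero_ok = TRUE)
    }
  }
  for (entry in lg) {
    if (entry$cols > max_cols) {
      viol[[length(viol) + 1L]] <- data.frame(
        step = entry$step, kind = entry$kind,
        problem = sprintf("payload has %d columns > cap %d", entry$cols, max_cols))
    }
    if (!is.null(raw_std) && entry$rows == d) {
      pc <- abs(tcrossprod(row_standardize(t(entry$payload), zero_ok = TRUE),
                           raw_std))
      if (any(pc > 1 - tol)) {
        viol[[length(viol) + 1L]] <- data.frame(
          step = entry$step, kind = entry$kind,
          problem = "payload column matches a raw subject column up to sign/scale")
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(step = integer(), kind = character(), problem = character())
  list(ok = nrow(violations) == 0, violations = violations)
}
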