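# DiffT: cumulative normalized difference between the co-membership
# (binarized) matrices of two partitions, with a per-bin permutation test
# to localize where topological change concentrates.

#' Co-membership (binarized) matrix of a partition
#'
#' Entry (i, j) is 1 iff bins i and j fall in the same domain.
#'
#' @param part matrix/data.frame with columns `start_bin`, `end_bin`
#'   (1-based inclusive) tiling `1..n`.
#' @param n number of bins.
#' @return n x n 0/1 matrix.
#' @export
binarize_partition <- function(part, n) {
  part <- as.matrix(part)
  validate_tiling(part, n)
  lab <- rep(seq_len(nrow(part)),
             part[, "end_bin"] - part[, "start_bin"] + 1L)
  outer(lab, lab, "==") * 1L
}

validate_tiling <- function(part, n) {
  starts <- part[, "start_bin"]; ends <- part[, "end_bin"]
  if (starts[1] != 1L || ends[length(ends)] != n ||
      any(ends < starts) ||
      (length(starts) > 1L && any(starts[-1] != ends[-length(ends)] + 1L)))
    stop(sprintf("partition does not tile bins 1..%d", n))
  invisible(TRUE)
}

# Per-bin row sum of |p_ij - q_ij| without forming the matrices:
# |P(i)| + |Q(i)| - 2 * |P(i) intersect Q(i)| for the domains holding i.
difft_rowdiff <- function(p, q, n) {
  p <- as.matrix(p); q <- as.matrix(q)
  ip <- findInterval(seq_len(n), p[, "start_bin"])
  iq <- findInterval(seq_len(n), q[, "start_bin"])
  ps <- p[ip, "start_bin"]; pe <- p[ip, "end_bin"]
  qs <- q[iq, "start_bin"]; qe <- q[iq, "end_bin"]
  ov <- pmax(0L, pmin(pe, qe) - pmax(ps, qs) + 1L)
  (pe - ps + 1L) + (qe - qs + 1L) - 2L * ov
}

#' DiffT profile between two partitions
#'
#' `DiffT(b) = sum_{i<=b} sum_{j<=N} |p_ij - q_ij| / sum over the full
#' square`, i.e. the cumulative fraction of the total co-membership
#' disagreement contributed by bins up to b. The profile is
#' non-decreasing and ends at exactly 1 whenever the partitions differ.
#'
#' @param p,q either co-membership matrices (from
#'   [binarize_partition()]) of equal size, or partitions (matrices with
#'   `start_bin`/`end_bin` columns) when `n` is given.
#' @param n number of bins (required when `p`, `q` are partitions).
#' @return numeric vector of length N with attribute `identical` set to
#'   TRUE (and an all-zero profile) when the partitions coincide.
#' @export
difft_profile <- function(p, q, n = NULL) {
  if (!is.null(n)) {
    validate_tiling(as.matrix(p), n); validate_tiling(as.matrix(q), n)
    rowdiff <- difft_rowdiff(p, q, n)
  } else {
    stopifnot(is.matrix(p), is.matrix(q), all(dim(p) == dim(q)))
    rowdiff <- rowSums(abs(p - q))
  }
  tot <- sum(rowdiff)
  if (tot == 0) {
    prof <- numeric(length(rowdiff))
    attr(prof, "identical") <- TRUE
    return(prof)
  }
  prof <- cumsum(rowdiff) / tot
  attr(prof, "identical") <- FALSE
  prof
}

#' Random contiguous partition
#'
#' Draws `k_domains - 1` distinct internal boundaries uniformly at random
#' from the positions not adjacent to an excluded bin (a boundary after
#' bin b is ineligible when bin b or bin b + 1 is excluded), yielding a
#' tiling partition.
#'
#' @param n number of bins.
#' @param k_domains number of domains.
#' @param excluded integer vector of excluded (bad) bins, 1-based.
#' @param seed optional integer seed (uses the global RNG stream when
#'   NULL).
#' @return integer matrix with columns `start_bin`, `end_bin`.
#' @export
random_partition <- function(n, k_domains, excluded = integer(0),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k_domains < 1L || k_domains > n) stop("k_domains out of range")
  if (k_domains == 1L)
    return(cbind(start_bin = 1L, end_bin = as.integer(n)))
  eligible <- setdiff(seq_len(n - 1L),
                      unique(c(excluded, excluded - 1L)))
  if (length(eligible) < k_domains - 1L)
    stop(sprintf("cannot place %d boundaries among %d eligible positions",
                 k_domains - 1L, length(eligible)))
  b <- sort(eligible[sample.int(length(eligible), k_domains - 1L)])
  cbind(start_bin = c(1L, b + 1L), end_bin = c(b, as.integer(n)))
}

#' Per-bin permutation significance of the DiffT score
#'
#' Simulates `n_sim` random partitions with the same domain count as `q`
#' (boundaries avoiding excluded bins), computes their DiffT profiles
#' against `p`, and estimates a per-bin p-value as the fraction of
#' simulated profiles lower than or equal to the observed q-vs-p profile
#' at that bin (with the add-one correction, so p-values lie in
#' `[1/(n_sim + 1), 1]`). The bin(s) attaining the minimum p-value mark
#' the start of the region holding the most significant share of the
#' topological difference.
#'
#' @param p,q partitions (matrices with `start_bin`/`end_bin` columns)
#'   tiling `1..n`.
#' @param n number of bins.
#' @param n_sim number of random partitions (default 10000).
#' @param excluded excluded bins forwarded to [random_partition()].
#' @param seed optional integer seed.
#' @return an object of class `difft_result`: `profile`, `pvalues`,
#'   `min_p_bins`, `n_sim`, `identical`.
#' @export
difft_significance <- function(p, q, n, n_sim = 10000L,
                               excluded = integer(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sim < 1L) stop("n_sim must be >= 1")
  p <- as.matrix(p); q <- as.matrix(q)
  prof <- difft_profile(p, q, n = n)
  if (attr(prof, "identical")) {
    return(structure(list(profile = prof, pvalues = NULL,
                          min_p_bins = integer(0), n_sim = 0L,
                          identical = TRUE),
                     class = "difft_result"))
  }
  k <- nrow(q)
  count <- integer(n)
  for (s in seq_len(n_sim)) {
    r <- random_partition(n, k, excluded = excluded)
    sim_prof <- difft_profile(p, r, n = n)
    count <- count + (sim_prof <= prof)
  }
  pv <- (count + 1) / (n_sim + 1)
  structure(list(profile = as.numeric(prof), pvalues = pv,
                 min_p_bins = which(pv == min(pv)),
                 n_sim = as.integer(n_sim), identical = FALSE),
            class = "difft_result")
}

#' @export
print.difft_result <- function(x, ...) {
  if (x$identical) {
    cat("difft_result: partitions identical (no test performed)\n")
  } else {
    cat(sprintf(
      "difft_result: %d bins, %d simulations, min p = %.4g at bin(s) %s\n",
      length(x$profile), x$n_sim, min(x$pvalues),
      paste(x$min_p_bins, collapse = ", ")))
  }
  invisible(x)
}
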