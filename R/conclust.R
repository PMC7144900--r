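# Constrained incremental sum-of-squares (CONISS) hierarchical clustering.
#
# Only genomically adjacent clusters may merge; the merge cost is the
# increase in within-cluster dispersion, where the dispersion of a
# cluster C is sum_{i<j in C} d_ij^2 / |C| (identical to the coordinate
# sum of squares when d is Euclidean). Costs are maintained with the
# Ward/Lance-Williams recurrence, giving O(n^2) overall; correctness is
# checked against a from-scratch oracle in the test suite.

#' Constrained incremental sum-of-squares clustering
#'
#' Agglomerates the n items (genomic bins, in order) into a dendrogram in
#' which every merge joins two clusters adjacent along the genome. At each
#' step the adjacent pair with the smallest dispersion increment is merged
#' (leftmost pair on ties).
#'
#' @param d symmetric distance matrix (zero diagonal, non-negative) or a
#'   `dist` object.
#' @return an object of class `coniss_dendrogram` with fields:
#'   `n` (leaf count); `merges` data.frame with one row per merge:
#'   `boundary` (the inter-item boundary removed, i.e. the merge joined
#'   the segments meeting between items `boundary` and `boundary + 1`),
#'   `increment` (dispersion increase) and `height` (cumulative
#'   dispersion after the merge); `hmerge` an `hclust`-style merge
#'   matrix.
#' @export
coniss <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-8 * max(d, 1))
    stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")

  # Segments live in slots indexed by their leftmost original item, so
  # slot order is genomic order and which.min() realizes the leftmost
  # tie-break. delta holds pairwise merge increments between all live
  # segments: the Lance-Williams update of a merged segment towards a
  # neighbour needs the increment between that neighbour and *both*
  # merged parts, one of which is not adjacent to it.
  delta <- d^2 / 2                     # singleton-pair merge increments
  sizes <- rep(1L, n)
  nxt <- c(seq_len(n)[-1], NA_integer_)
  prv <- c(NA_integer_, seq_len(n - 1))
  active <- rep(TRUE, n)
  cost <- c(delta[cbind(1:(n - 1), 2:n)], Inf)  # cost[i]: merge i with nxt[i]

  merges <- data.frame(boundary = integer(n - 1),
                       increment = numeric(n - 1),
                       height = numeric(n - 1))
  hmerge <- matrix(0L, n - 1, 2)
  seg_node <- -seq_len(n)              # hclust ids: -leaf or +merge step
  total <- 0
  for (step in seq_len(n - 1)) {
    i <- which.min(cost)               # leftmost minimal adjacent pair
    j <- nxt[i]
    inc <- cost[i]
    total <- total + inc
    merges$boundary[step] <- j - 1L    # boundary between items j-1 and j
    merges$increment[step] <- inc
    merges$height[step] <- total
    hmerge[step, ] <- sort(c(seg_node[i], seg_node[j]))

    na <- sizes[i]; nb <- sizes[j]
    others <- which(active); others <- others[others != i & others != j]
    if (length(others)) {
      nc <- sizes[others]
      new_delta <- ((na + nc) * delta[i, others] +
                    (nb + nc) * delta[j, others] -
                    nc * inc) / (na + nb + nc)
      delta[i, others] <- new_delta
      delta[others, i] <- new_delta
    }
    sizes[i] <- na + nb
    seg_node[i] <- step
    active[j] <- FALSE
    cost[j] <- Inf
    nxt[i] <- nxt[j]
    if (!is.na(nxt[j])) prv[nxt[j]] <- i
    cost[i] <- if (is.na(nxt[i])) Inf else delta[i, nxt[i]]
    if (!is.na(prv[i])) cost[prv[i]] <- delta[prv[i], i]
  }
  structure(list(n = n, merges = merges, hmerge = hmerge),
            class = "coniss_dendrogram")
}

#' @export
print.coniss_dendrogram <- function(x, ...) {
  cat(sprintf("coniss_dendrogram: %d leaves, total dispersion %.4g\n",
              x$n, x$merges$height[x$n - 1]))
  invisible(x)
}

#' Convert a CONISS dendrogram to an hclust object
#'
#' Heights are the cumulative within-group dispersions, so the tree is
#' guaranteed monotone and can be plotted with the standard machinery.
#'
#' @param x a `coniss_dendrogram`.
#' @param ... unused.
#' @return an `hclust` object.
#' @export
as.hclust.coniss_dendrogram <- function(x, ...) {
  structure(list(merge = x$hmerge, height = x$merges$height,
                 order = seq_len(x$n),
                 labels = NULL, method = "coniss",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a CONISS dendrogram into k contiguous segments
#'
#' Undoes the last k - 1 merges. Because merging is adjacency
#' constrained, the result is always a tiling of the region by k
#' contiguous segments in genomic order.
#'
#' @param dend a `coniss_dendrogram`.
#' @param k number of clusters, 1 <= k <= n.
#' @return integer matrix with one row per segment and columns
#'   `start_bin`, `end_bin` (1-based, inclusive).
#' @export
cut_coniss <- function(dend, k) {
  stopifnot(inherits(dend, "coniss_dendrogram"))
  n <- dend$n
  if (k < 1L || k > n) stop(sprintf("k must lie in [1, %d]", n))
  bounds <- if (k == 1L) integer(0) else
    sort(dend$merges$boundary[seq(n - 1L, by = -1L, length.out = k - 1L)])
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  cbind(start_bin = starts, end_bin = ends)
}

#' Segment membership labels for a dendrogram cut
#'
#' @inheritParams cut_coniss
#' @return integer vector of length n assigning each item to a segment
#'   (numbered left to right).
#' @export
cut_coniss_labels <- function(dend, k) {
  seg <- cut_coniss(dend, k)
  rep(seq_len(nrow(seg)), seg[, "end_bin"] - seg[, "start_bin"] + 1L)
}
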