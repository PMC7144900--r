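# Level selection: broken-stick significance bound, Calinski-Harabasz
# scoring across retained-PC counts, and the joint (N_PC*, level*) choice.

cond_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("hictad_undefined", "error")))
}

#' Broken-stick pieces
#'
#' Expected sorted fractions when a unit stick is broken into `n` random
#' pieces: `b_g = (1/n) * sum_{i=g}^{n} 1/i`. The pieces sum to 1.
#'
#' @param n number of pieces.
#' @return numeric vector of length `n`, decreasing.
#' @export
broken_stick_pieces <- function(n) {
  stopifnot(n >= 1)
  rev(cumsum(rev(1 / seq_len(n)))) / n
}

#' Maximum significant hierarchy level under the broken-stick model
#'
#' For each group count g = 2..n the observed fraction of total
#' dispersion released by the g-th split (the increment of the merge the
#' cut undoes, divided by the total dispersion) is compared against the
#' broken-stick expectation for piece g of an n-piece stick. The maximum
#' significant number of groups G is the largest g such that observed >
#' expected for every 2..g (the scan stops at the first crossing when
#' `first_crossing = TRUE`, the default; otherwise the largest
#' individually significant g is taken). The returned maximum level is
#' G - 1, level L meaning a partition into L + 1 domains; 0 means no
#' significant hierarchy.
#'
#' @param dend a `coniss_dendrogram` with at least 3 leaves.
#' @param first_crossing stop at the first non-significant split
#'   (default) instead of accepting any significant one.
#' @return integer, maximum significant level (possibly 0).
#' @export
broken_stick_max_level <- function(dend, first_crossing = TRUE) {
  stopifnot(inherits(dend, "coniss_dendrogram"))
  n <- dend$n
  if (n < 3L) stop("need at least 3 leaves for the broken-stick bound")
  total <- dend$merges$height[n - 1L]
  if (total <= 0) return(0L)
  bs <- broken_stick_pieces(n)
  # split into g groups undoes merge n - g + 1
  observed <- dend$merges$increment[seq(n - 1L, 1L)] / total
  signif <- observed > bs[2:n]
  if (first_crossing) {
    g_max <- if (!signif[1]) 1L else which.min(c(signif, FALSE)) # run length+1
  } else {
    g_max <- if (!any(signif)) 1L else max(which(signif)) + 1L
  }
  as.integer(g_max - 1L)
}

#' Calinski-Harabasz index
#'
#' `CH = [B / (k - 1)] / [W / (n - k)]` where B is the between-cluster
#' sum of squared deviations of cluster centroids from the grand centroid
#' (weighted by cluster size) and W the within-cluster sum of squared
#' deviations.
#'
#' @param points n x p numeric matrix (rows = observations).
#' @param labels cluster assignment of length n; every cluster non-empty.
#' @return the CH index; undefined for k = 1 or k = n (a condition of
#'   class `hictad_undefined` is signalled).
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L || k >= n)
    cond_undefined(sprintf("CH index undefined for k = %d with n = %d", k, n))
  grand <- colMeans(points)
  W <- 0; B <- 0
  for (g in seq_len(k)) {
    pg <- points[labels == g, , drop = FALSE]
    cg <- colMeans(pg)
    W <- W + sum(sweep(pg, 2, cg)^2)
    B <- B + nrow(pg) * sum((cg - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Map a partition of filtered bins back to original bin coordinates
#'
#' Boundaries are carried through the kept-to-original index map. Masked
#' bins falling between two domains are attached to the preceding
#' domain; leading masked bins attach to the first domain and trailing
#' ones to the last, so the result tiles all original bins.
#'
#' @param part matrix/data.frame with columns `start_bin`, `end_bin`
#'   (1-based inclusive) tiling the filtered bins.
#' @param bm a `bin_map` (NULL for identity).
#' @return integer matrix with columns `start_bin`, `end_bin` tiling
#'   `1..n_original`.
#' @export
map_partition <- function(part, bm = NULL) {
  part <- as.matrix(part)
  if (is.null(bm))
    return(cbind(start_bin = as.integer(part[, "start_bin"]),
                 end_bin = as.integer(part[, "end_bin"])))
  stopifnot(inherits(bm, "bin_map"))
  k2o <- bm$kept_to_original
  nk <- nrow(part)
  ends <- integer(nk)
  ends[nk] <- bm$n_original
  if (nk > 1L)
    ends[-nk] <- k2o[part[-1L, "start_bin"]] - 1L
  starts <- c(1L, ends[-nk] + 1L)
  cbind(start_bin = starts, end_bin = ends)
}

#' Convert a bin partition to genomic (bp) intervals
#'
#' @param part matrix with columns `start_bin`, `end_bin` (1-based
#'   inclusive bins).
#' @param chrom chromosome label.
#' @param start_bp genomic position of the first bin (0-based).
#' @param resolution bin size (bp).
#' @return data.frame `chrom`, `start`, `end` with 0-based half-open
#'   (BED) coordinates.
#' @export
partition_to_bp <- function(part, chrom, start_bp, resolution) {
  part <- as.matrix(part)
  data.frame(chrom = chrom,
             start = start_bp + (part[, "start_bin"] - 1) * resolution,
             end = start_bp + part[, "end_bin"] * resolution)
}

#' Joint selection of retained PCs and hierarchy level
#'
#' Sweeps the number of retained principal components from 1 to the
#' numerical rank (capped at `n_pc_max`). For each count it builds the
#' Euclidean distance matrix, runs CONISS, bounds the significant levels
#' with the broken-stick model, and scores every significant level with
#' the CH index on the retained scores. The component count whose
#' dendrogram has the highest mean CH over its significant levels wins
#' (smallest count on ties); within the winner the level with maximal CH
#' is optimal (smallest on ties). The optimal number of TADs is the
#' optimal level plus one.
#'
#' @param filtered a filtered `ContactMatrix` (no masked bins), e.g. the
#'   `matrix` element of [drop_masked()].
#' @param bm the accompanying `bin_map` (NULL when nothing was filtered).
#' @param n_pc_max maximum retained components (default 200).
#' @param min_tads only levels with at least this many domains enter the
#'   CH averaging and the optimum (default 2; the technical benchmark
#'   setting is 10).
#' @param first_crossing passed to [broken_stick_max_level()].
#' @return an object of class `tad_hierarchy`; if no component count
#'   yields a significant level, a flagged "no hierarchy" object
#'   (`no_hierarchy = TRUE`) is returned rather than an error. The
#'   `support` field gives the fraction of swept component counts with
#'   at least one significant level; results with support below 50% are
#'   flagged `stable = FALSE` (isolated broken-stick crossings on
#'   structureless matrices).
#' @export
tad_hierarchy <- function(filtered, bm = NULL, n_pc_max = 200L,
                          min_tads = 2L, first_crossing = TRUE) {
  stopifnot(inherits(filtered, "ContactMatrix"))
  if (any(filtered$bad_mask))
    stop("`filtered` still contains masked bins; run drop_masked() first")
  pcc <- pearson_transform(filtered)
  emb <- pca_reduce(pcc, n_pc_max = n_pc_max)
  n <- n_bins(filtered)
  n_avail <- emb$n_pc
  max_lv <- integer(n_avail)
  ch_rows <- vector("list", n_avail)
  for (np in seq_len(n_avail)) {
    d <- euclidean_distance_matrix(emb, np)
    dend <- coniss(d)
    ml <- min(broken_stick_max_level(dend, first_crossing), n - 2L)
    max_lv[np] <- ml
    if (ml >= 1L) {
      ch <- vapply(seq_len(ml), function(L) {
        calinski_harabasz(emb$scores[, seq_len(np), drop = FALSE],
                          cut_coniss_labels(dend, L + 1L))
      }, numeric(1))
      ch_rows[[np]] <- ch
    }
  }
  width <- max(max_lv, 0L)
  ch_matrix <- matrix(NA_real_, n_avail, width,
                      dimnames = list(paste0("PC", seq_len(n_avail)),
                                      if (width) paste0("L", seq_len(width))))
  for (np in seq_len(n_avail))
    if (max_lv[np] >= 1L)
      ch_matrix[np, seq_len(max_lv[np])] <- ch_rows[[np]]
  # eligibility: level L has L + 1 domains
  lv_ok <- function(L) (L + 1L) >= min_tads
  mean_ch <- rep(NA_real_, n_avail)
  for (np in seq_len(n_avail)) {
    if (max_lv[np] < 1L) next
    lv <- seq_len(max_lv[np]); lv <- lv[lv_ok(lv)]
    if (length(lv)) mean_ch[np] <- mean(ch_matrix[np, lv])
  }
  # stability: a real hierarchical signal is detectable across most of
  # the PC sweep; isolated broken-stick crossings mark spurious finds
  support <- mean(max_lv >= 1L)
  out <- structure(
    list(chrom = filtered$chrom, start_bp = filtered$start_bp,
         resolution = filtered$resolution,
         bin_map = bm, n_bins_filtered = n,
         n_bins_original = if (is.null(bm)) n else bm$n_original,
         explained_variance = emb$explained_variance,
         ch_matrix = ch_matrix, mean_ch = mean_ch,
         support = support, stable = support >= 0.5,
         no_hierarchy = TRUE, n_pc_opt = NA_integer_,
         max_level = 0L, optimal_level = NA_integer_,
         n_tads_opt = NA_integer_, levels = list(), dendrogram = NULL),
    class = "tad_hierarchy")
  if (all(is.na(mean_ch))) return(out)

  n_pc_opt <- which.max(ifelse(is.na(mean_ch), -Inf, mean_ch))
  dend <- coniss(euclidean_distance_matrix(emb, n_pc_opt))
  ml <- max_lv[n_pc_opt]
  lv_all <- seq_len(ml)
  lv_elig <- lv_all[lv_ok(lv_all)]
  ch_win <- ch_matrix[n_pc_opt, lv_all]
  opt <- lv_elig[which.max(ch_win[lv_elig])]
  levels <- lapply(lv_all, function(L) {
    p <- map_partition(cut_coniss(dend, L + 1L), bm)
    attr(p, "level") <- L
    attr(p, "ch") <- ch_win[L]
    p
  })
  out$no_hierarchy <- FALSE
  out$n_pc_opt <- as.integer(n_pc_opt)
  out$max_level <- as.integer(ml)
  out$optimal_level <- as.integer(opt)
  out$n_tads_opt <- as.integer(opt + 1L)
  out$levels <- levels
  out$dendrogram <- dend
  out
}

#' @export
print.tad_hierarchy <- function(x, ...) {
  if (x$no_hierarchy) {
    cat(sprintf("tad_hierarchy: %s - no significant hierarchy detected\n",
                x$chrom))
  } else if (!x$stable) {
    cat(sprintf(
      "tad_hierarchy: %s - WEAK hierarchy (significant levels for only %.0f%% of the PC sweep)\n  optimal PCs: %d | optimal level: %d (%d TADs)\n",
      x$chrom, 100 * x$support, x$n_pc_opt, x$optimal_level, x$n_tads_opt))
  } else {
    cat(sprintf(
      "tad_hierarchy: %s, %d bins (%d after filtering)\n  optimal PCs: %d | significant levels: %d | optimal level: %d (%d TADs, CH = %.2f)\n",
      x$chrom, x$n_bins_original, x$n_bins_filtered, x$n_pc_opt,
      x$max_level, x$optimal_level, x$n_tads_opt,
      attr(x$levels[[x$optimal_level]], "ch")))
  }
  invisible(x)
}

#' Extract one level of a hierarchy as a bin partition
#'
#' @param h a `tad_hierarchy`.
#' @param level level number (default: the optimal level).
#' @return integer matrix with columns `start_bin`, `end_bin` in
#'   original bin coordinates.
#' @export
hierarchy_level <- function(h, level = h$optimal_level) {
  stopifnot(inherits(h, "tad_hierarchy"))
  if (h$no_hierarchy) stop("no significant hierarchy in this object")
  if (is.na(level) || level < 1L || level > h$max_level)
    stop(sprintf("level must lie in [1, %d]", h$max_level))
  h$levels[[level]]
}
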