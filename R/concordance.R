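# Partition-comparison metrics: Measure of Concordance and the border
# overlap score with its random-partition p-value.

validate_domain_set <- function(x, name = deparse(substitute(x))) {
  x <- as.data.frame(x)
  if (!all(c("start", "end") %in% names(x)))
    stop(sprintf("%s needs `start` and `end` columns (bp, half-open)", name))
  if (any(x$end <= x$start)) stop(sprintf("%s has empty domains", name))
  if (nrow(x) > 1L && any(x$start[-1] != x$end[-nrow(x)]))
    stop(sprintf("%s is not contiguous/sorted", name))
  x
}

#' Measure of Concordance between two genome partitions
#'
#' `MoC(P, Q) = 1` when both partitions consist of a single domain;
#' otherwise `(1 / (sqrt(N_P N_Q) - 1)) * (sum_ij F_ij^2 / (|P_i| |Q_j|)
#' - 1)` where `F_ij` is the base-pair overlap between domains `P_i` and
#' `Q_j`. Ranges from 0 (discordant) to 1 (identical partitions).
#'
#' @param p,q domain sets: data.frames with `start`/`end` columns in bp
#'   (0-based half-open), contiguous and covering the same extent.
#' @return MoC in \[0, 1\].
#' @export
moc <- function(p, q) {
  p <- validate_domain_set(p, "p"); q <- validate_domain_set(q, "q")
  if (p$start[1] != q$start[1] || p$end[nrow(p)] != q$end[nrow(q)])
    stop("partitions cover different extents")
  np <- nrow(p); nq <- nrow(q)
  if (np == 1L && nq == 1L) return(1)
  acc <- 0
  for (i in seq_len(np)) {
    ov <- pmax(0, pmin(p$end[i], q$end) - pmax(p$start[i], q$start))
    sz_p <- p$end[i] - p$start[i]
    acc <- acc + sum(ov^2 / (sz_p * (q$end - q$start)))
  }
  (acc - 1) / (sqrt(np * nq) - 1)
}

#' Internal borders of a domain set
#'
#' Region-terminal positions are excluded: they are shared by
#' construction and would inflate any overlap statistic.
#'
#' @param x a domain set (bp).
#' @return numeric vector of internal boundary positions (bp).
#' @export
internal_borders <- function(x) {
  x <- validate_domain_set(x, "x")
  if (nrow(x) < 2L) return(numeric(0))
  x$end[-nrow(x)]
}

# fraction (x100) of coarse borders with a sorted fine border within tol;
# eps must be below the border-position granularity (half a resolution)
border_overlap_pct <- function(fine_borders, coarse_borders, tol, eps) {
  hi <- findInterval(coarse_borders + tol, fine_borders)
  lo <- findInterval(coarse_borders - tol - eps, fine_borders)
  100 * mean(hi > lo)
}

#' Border overlap score between a fine and a coarse partition
#'
#' Percentage of the coarse partition's internal borders that have a
#' fine-partition internal border within `tol_bins` bins of the finer
#' resolution.
#'
#' @param fine,coarse domain sets (bp) on the same span.
#' @param tol_bins tolerance in fine-resolution bins (default 1).
#' @param resolution bin size of the finer partition (bp).
#' @return percentage in \[0, 100\].
#' @export
overlap_score <- function(fine, coarse, tol_bins = 1L, resolution) {
  bf <- internal_borders(fine)
  bc <- internal_borders(coarse)
  if (length(bf) == 0L || length(bc) == 0L)
    cond_undefined("overlap score undefined without internal borders")
  border_overlap_pct(sort(bf), bc, tol_bins * resolution, resolution / 2)
}

#' Permutation p-value for a border overlap score
#'
#' Draws `n_rand` random partitions at the finer resolution with the same
#' domain count as the observed fine partition and computes the fraction
#' with an overlap score greater than or equal to the observed one
#' (add-one corrected).
#'
#' @inheritParams overlap_score
#' @param n_rand number of random partitions (default 10000).
#' @param seed optional integer seed.
#' @return list with `p_value`, `observed` (score) and `n_rand`.
#' @export
overlap_pvalue <- function(fine, coarse, tol_bins = 1L, resolution,
                           n_rand = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_rand < 1L) stop("n_rand must be >= 1")
  fine <- validate_domain_set(fine, "fine")
  observed <- overlap_score(fine, coarse, tol_bins, resolution)
  span0 <- fine$start[1]
  n_bins <- as.integer(round((fine$end[nrow(fine)] - span0) / resolution))
  k <- nrow(fine)
  bc <- internal_borders(coarse)
  tol <- tol_bins * resolution
  hits <- 0L
  for (s in seq_len(n_rand)) {
    r <- random_partition(n_bins, k)
    rb <- span0 + r[-nrow(r), "end_bin"] * resolution
    sc <- border_overlap_pct(rb, bc, tol, resolution / 2)
    if (sc >= observed) hits <- hits + 1L
  }
  list(p_value = (hits + 1) / (n_rand + 1), observed = observed,
       n_rand = as.integer(n_rand))
}
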