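# Independent brute-force oracles used to pin down expected values.

# From-scratch constrained agglomeration: recomputes every cluster's
# dispersion (sum of squared pairwise distances over cluster size) at
# every step and scans all adjacent pairs. O(n^4)-ish; for tiny n only.
oracle_coniss <- function(d) {
  d2 <- d^2
  n <- nrow(d)
  disp <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- d2[idx, idx]
    sum(s[upper.tri(s)]) / length(idx)
  }
  segs <- lapply(seq_len(n), identity)
  out <- NULL
  total <- 0
  states <- list(segs)
  while (length(segs) > 1) {
    incs <- vapply(seq_len(length(segs) - 1), function(i) {
      disp(c(segs[[i]], segs[[i + 1]])) - disp(segs[[i]]) - disp(segs[[i + 1]])
    }, numeric(1))
    i <- which.min(incs)
    total <- total + incs[i]
    out <- rbind(out, c(boundary = max(segs[[i]]), increment = incs[i],
                        height = total))
    segs[[i]] <- c(segs[[i]], segs[[i + 1]])
    segs[[i + 1]] <- NULL
    states[[length(states) + 1]] <- segs
  }
  list(merges = as.data.frame(out), states = states)
}

# DiffT profile by literal double loop over both full binarized matrices.
oracle_difft <- function(pmat, qmat) {
  n <- nrow(pmat)
  tot <- 0
  rows <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    rows[i] <- rows[i] + abs(pmat[i, j] - qmat[i, j])
  }
  tot <- sum(rows)
  if (tot == 0) return(numeric(n))
  cumsum(rows) / tot
}

# CH index from the definition sums, no shortcuts.
oracle_ch <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  ids <- unique(labels)
  k <- length(ids)
  grand <- colMeans(points)
  B <- 0; W <- 0
  for (g in ids) {
    pg <- points[labels == g, , drop = FALSE]
    cg <- colMeans(pg)
    B <- B + nrow(pg) * sum((cg - grand)^2)
    for (r in seq_len(nrow(pg))) W <- W + sum((pg[r, ] - cg)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Linear-interpolation percentile (type 7) written out by hand.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# random contiguous bin partition as a start/end matrix (test-local)
rand_part <- function(n, k) random_partition(n, k)

# write a matrix to a temp TSV and return the path
write_tmp_matrix <- function(vals, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(vals, f, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  f
}
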