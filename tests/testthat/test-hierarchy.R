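test_that("broken-stick pieces follow the analytic formula", {
  b <- broken_stick_pieces(3)
  expect_equal(b, c(11, 5, 2) / 18)
  expect_equal(sum(b), 1)
  expect_equal(sum(broken_stick_pieces(25)), 1)
  expect_true(all(diff(broken_stick_pieces(25)) < 0))
})

test_that("broken-stick bound is 0 when no split beats expectation", {
  # regular-simplex geometry: every merge increment is identical, so the
  # first split explains 1/(n-1) < b_2 and nothing is significant
  d <- as.matrix(dist(diag(8) * 5))
  dend <- coniss(d)
  expect_equal(dend$merges$increment, rep(dend$merges$increment[1], 7),
               tolerance = 1e-9)
  expect_equal(broken_stick_max_level(dend), 0L)
})

test_that("broken-stick finds the planted split of a 2-block matrix", {
  g <- generate_matrix(synthetic_spec(n_bins = 40, levels = list(20L),
                                      bad_column_fraction = 0, seed = 91))
  f <- drop_masked(detect_bad_columns(g$matrix))
  e <- pca_reduce(pearson_transform(f$matrix))
  dend <- coniss(euclidean_distance_matrix(e, 2))
  expect_gte(broken_stick_max_level(dend), 1L)
  expect_equal(cut_coniss(dend, 2)[1, "end_bin"], 20L, ignore_attr = TRUE)
})

test_that("CH index matches definition sums and limiting behaviour", {
  pts <- cbind(c(0, 0.01, 10, 10.01))
  expect_gt(calinski_harabasz(pts, c(1, 1, 2, 2)), 1e6)

  set.seed(92)
  p6 <- matrix(rnorm(12), 6, 2)
  lab <- c(1, 1, 2, 2, 3, 3)
  expect_equal(calinski_harabasz(p6, lab), oracle_ch(p6, lab),
               tolerance = 1e-12)

  expect_error(calinski_harabasz(p6, rep(1, 6)), class = "hictad_undefined")
  expect_error(calinski_harabasz(p6, 1:6), class = "hictad_undefined")
})

test_that("CH is ~1 in expectation under random labels on one blob", {
  set.seed(93)
  pts <- matrix(rnorm(600), 300, 2)
  chs <- replicate(300, calinski_harabasz(pts, sample(rep(1:4, 75))))
  expect_lt(abs(mean(chs) - 1), 0.1)
})

test_that("map_partition reinserts masked bins onto the preceding domain", {
  part <- cbind(start_bin = c(1L, 3L), end_bin = c(2L, 4L))
  expect_equal(map_partition(part, NULL), part)

  # mask [F,F,T,F]: boundary after filtered bin 2 lands after original
  # bin 3 (the masked bin 3 is absorbed leftward)
  bm <- bin_map(c(1L, 2L, 4L), 4L)
  p <- cbind(start_bin = c(1L, 3L), end_bin = c(2L, 3L))
  mapped <- map_partition(p, bm)
  expect_equal(mapped[, "end_bin"], c(3L, 4L), ignore_attr = TRUE)
  expect_equal(mapped[, "start_bin"], c(1L, 4L), ignore_attr = TRUE)

  # monotone tiling is preserved through arbitrary masks
  set.seed(94)
  for (r in 1:20) {
    n <- 30L
    keep <- sort(sample(n, 22))
    bm2 <- bin_map(keep, n)
    k <- sample(2:6, 1)
    part2 <- random_partition(22L, k)
    m2 <- map_partition(part2, bm2)
    expect_equal(m2[1, "start_bin"], 1L, ignore_attr = TRUE)
    expect_equal(m2[k, "end_bin"], n, ignore_attr = TRUE)
    if (k > 1)
      expect_equal(m2[-1, "start_bin"], m2[-k, "end_bin"] + 1L,
                   ignore_attr = TRUE)
  }
})

test_that("tad_hierarchy recovers planted structure deterministically", {
  g <- generate_matrix(synthetic_spec(seed = 95))
  h1 <- call_tads(g$matrix)
  h2 <- call_tads(g$matrix)
  expect_identical(h1, h2)  # bitwise determinism

  expect_false(h1$no_hierarchy)
  expect_true(h1$stable)
  expect_equal(h1$n_tads_opt, h1$optimal_level + 1L)
  opt <- hierarchy_level(h1)
  truth_moc <- max(vapply(g$truth, function(tr) {
    moc(partition_to_bp(opt, "c", 0, 1), partition_to_bp(tr, "c", 0, 1))
  }, numeric(1)))
  expect_gte(truth_moc, 0.9)
})

test_that("multi-PC dendrogram cuts recover all planted levels within 1 bin", {
  sp <- synthetic_spec(n_bins = 96, levels = list(48L, c(24L, 48L, 72L),
                                                  c(12L, 24L, 36L, 48L,
                                                    60L, 72L, 84L)),
                       bad_column_fraction = 0, seed = 96)
  g <- generate_matrix(sp)
  f <- drop_masked(detect_bad_columns(g$matrix))
  e <- pca_reduce(pearson_transform(f$matrix))
  dend <- coniss(euclidean_distance_matrix(e, 10))
  for (lv in seq_along(sp$levels)) {
    k <- length(sp$levels[[lv]]) + 1L
    cuts <- cut_coniss(dend, k)[-k, "end_bin"]
    expect_true(all(abs(cuts - sp$levels[[lv]]) <= 1),
                label = sprintf("level %d boundaries", lv))
  }
})

test_that("levels of one dendrogram are nested", {
  g <- generate_matrix(synthetic_spec(seed = 97, bad_column_fraction = 0))
  f <- drop_masked(detect_bad_columns(g$matrix))
  e <- pca_reduce(pearson_transform(f$matrix))
  dend <- coniss(euclidean_distance_matrix(e, 5))
  ml <- broken_stick_max_level(dend)
  bounds <- function(k) cut_coniss(dend, k)[-k, "end_bin"]
  for (L in seq_len(max(ml - 1L, 0L)))
    expect_true(all(bounds(L + 1L) %in% bounds(L + 2L)))
})

test_that("ch_matrix is finite where defined and optimum attains row max", {
  g <- generate_matrix(synthetic_spec(seed = 98))
  h <- call_tads(g$matrix)
  expect_true(all(is.finite(h$ch_matrix[!is.na(h$ch_matrix)])))
  row <- h$ch_matrix[h$n_pc_opt, ]
  expect_equal(attr(h$levels[[h$optimal_level]], "ch"),
               max(row, na.rm = TRUE))
})

test_that("structureless input is flagged", {
  set.seed(99)
  g <- generate_matrix(synthetic_spec(block_contrast = 1,
                                      bad_column_fraction = 0, seed = 99))
  v <- g$matrix$values
  perm <- sample(nrow(v))
  h <- call_tads(contact_matrix(v[perm, perm]))
  expect_true(h$no_hierarchy || !h$stable)
})

test_that("min_tads restricts the competition to deep levels", {
  g <- generate_matrix(synthetic_spec(seed = 100))
  h <- call_tads(g$matrix, min_tads = 4L)
  if (!h$no_hierarchy) expect_gte(h$n_tads_opt, 4L)
})
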