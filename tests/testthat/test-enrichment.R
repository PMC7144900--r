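test_that("spp_profile places peaks in the right slots", {
  # single boundary, single 1-kb peak 7 kb downstream: second positive slot
  prof <- spp_profile(2e6, data.frame(start = 2e6 + 7000, end = 2e6 + 8000))
  expect_equal(length(prof), 200L)
  hit <- which(prof > 0)
  expect_equal(as.numeric(names(prof)[hit]), 5000)
  expect_equal(as.numeric(prof[hit]), 1)

  # peaks exactly at every boundary -> maximal at offset 0
  bounds <- c(2e6, 4e6, 6e6)
  pk <- data.frame(start = bounds, end = bounds + 400)
  prof2 <- spp_profile(bounds, pk)
  expect_equal(as.numeric(prof2[["0"]]), max(prof2))
  expect_error(spp_profile(numeric(0), pk), "no boundaries")
})

test_that("spp_profile is translation-equivariant and flat under uniformity", {
  set.seed(131)
  bounds <- seq(1e6, 9e6, by = 2e6)
  pk <- data.frame(start = sort(runif(300, 0, 1e7)), end = NA)
  pk$end <- pk$start + 300
  prof <- spp_profile(bounds, pk)
  shift <- 123456
  prof_shift <- spp_profile(bounds + shift,
                            data.frame(start = pk$start + shift,
                                       end = pk$end + shift))
  expect_equal(as.numeric(prof), as.numeric(prof_shift))

  # uniform peaks: center slot within 3 sigma of the Poisson slot mean
  lambda <- 300 * 5300 / 1e7           # ~rate of peaks touching a slot
  sigma <- sqrt(lambda / length(bounds))
  expect_lt(abs(prof[["0"]] - lambda), 3 * sigma)
})

test_that("spp_fold_change does window arithmetic as documented", {
  mk_prof <- function(vals) {
    names(vals) <- seq(-5e5, by = 5000, length.out = 200)
    attr(vals, "step") <- 5000; attr(vals, "half_window") <- 5e5
    vals
  }
  expect_equal(spp_fold_change(mk_prof(rep(2, 200))), 0)

  v <- rep(1, 200)
  v[100:102] <- 2   # center slot (101) plus/minus one
  expect_equal(spp_fold_change(mk_prof(v)), 1)

  # hand-built asymmetric fixture: center mean 4, background mean 1.5
  v2 <- rep(0, 200)
  v2[100:102] <- 4
  v2[1:20] <- 1       # [-500, -400) kb flank
  v2[181:200] <- 2    # [400, 500) kb flank
  expect_equal(spp_fold_change(mk_prof(v2)), 4 / 1.5 - 1)

  expect_error(spp_fold_change(mk_prof(rep(0, 200))),
               class = "hictad_undefined")
})

test_that("boundary occupancy counts covered boundaries", {
  bounds <- c(1e5, 2e5, 3e5, 4e5, 5e5)
  pk <- data.frame(start = c(1e5 - 100, 3e5 + 500), end = c(1e5, 3e5 + 900))
  expect_equal(boundary_occupancy(bounds, pk, 1, 1e4), 0.4)  # 2 of 5
  expect_equal(boundary_occupancy(bounds,
                                  data.frame(start = bounds - 50,
                                             end = bounds + 50), 1, 1e4), 1)
  expect_equal(boundary_occupancy(bounds,
                                  data.frame(start = 9e5, end = 9.1e5),
                                  1, 1e4), 0)
  # monotone under peak addition
  set.seed(132)
  pks <- data.frame(start = runif(20, 0, 6e5), end = NA)
  pks$end <- pks$start + 200
  occ <- sapply(1:20, function(k)
    boundary_occupancy(bounds, pks[1:k, ], 1, 1e4))
  expect_true(all(diff(occ) >= 0))
})

test_that("consensus and union follow interval arithmetic", {
  a <- data.frame(start = c(0, 100), end = c(50, 200))
  cu1 <- consensus_and_union(list(a))
  expect_equal(cu1$union[, c("start", "end")], a, ignore_attr = TRUE)
  expect_equal(cu1$consensus[, c("start", "end")], a, ignore_attr = TRUE)

  b <- data.frame(start = 300, end = 400)
  cu2 <- consensus_and_union(list(a, b))
  expect_equal(nrow(cu2$consensus), 0)

  # partial overlaps versus a coverage-vector (sweep-line) oracle
  reps <- list(data.frame(start = c(0, 60), end = c(30, 90)),
               data.frame(start = c(10, 55), end = c(40, 80)))
  cu3 <- consensus_and_union(reps)
  cover <- function(df) {
    v <- logical(100)
    for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
    v
  }
  cov_all <- cover(reps[[1]]) & cover(reps[[2]])
  cov_any <- cover(reps[[1]]) | cover(reps[[2]])
  expect_equal(cover(cu3$consensus), cov_all)
  expect_equal(cover(cu3$union), cov_any)
})

test_that("tad_state_test separates aligned, identical and null worlds", {
  tads <- data.frame(start = seq(0, 7e5, by = 1e5),
                     end = seq(1e5, 8e5, by = 1e5))
  tr <- generate_signal_tracks(tads, 1000, seed = 133)
  st <- tad_state_test(tads, tr$repressive, tr$active, n_shuffle = 500,
                       seed = 134)
  expect_gte(st$fraction, 0.9)
  expect_equal(st$coarse_bin, 1e4)

  same <- signal_track(rep(5, 800), 1000, 0)
  st0 <- tad_state_test(tads, same, same, n_shuffle = 200, seed = 135)
  expect_equal(st0$fraction, 0)

  # exchangeable-noise null: fraction near the FDR level
  set.seed(136)
  fr <- replicate(40, {
    x <- signal_track(exp(rnorm(800, 0, 0.5)), 1000, 0)
    y <- signal_track(exp(rnorm(800, 0, 0.5)), 1000, 0)
    tad_state_test(tads, x, y, n_shuffle = 400)$fraction
  })
  expect_lt(abs(mean(fr) - 0.1), 0.08)
})
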