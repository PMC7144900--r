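# Synthetic nested block-structured contact matrices with known ground
# truth, plus matched peak and signal fixtures. The generator emulates
# the two signal features the caller relies on: a power-law decay of
# expected counts with genomic distance, and multiplicative contact
# enrichment inside nested domains.

#' Specification of a synthetic nested contact matrix
#'
#' Defaults describe the reference test world: a 96-bin region with a
#' two-level nested hierarchy (2 domains splitting into 4), strong block
#' contrast, unit distance-decay exponent and Poisson counting noise.
#'
#' @param n_bins number of bins (default 96).
#' @param levels list of boundary sets, one per hierarchy level, each an
#'   increasing vector of internal boundaries (boundary b separates bins
#'   b and b + 1, 1-based). Sets must be nested: every boundary of level
#'   l must appear in level l + 1.
#' @param block_contrast multiplicative enrichment applied once per
#'   shared nesting depth (default 3).
#' @param distance_decay_exponent power-law exponent alpha of the
#'   expected-count decay with bin distance (default 1).
#' @param base expected count at unit distance outside all blocks
#'   (default 100).
#' @param bad_column_fraction fraction of columns zeroed to emulate bad
#'   columns (default 0.02).
#' @param seed optional integer seed used by [generate_matrix()].
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 96L,
                           levels = list(c(48L), c(24L, 48L, 72L)),
                           block_contrast = 3,
                           distance_decay_exponent = 1,
                           base = 100,
                           bad_column_fraction = 0.02,
                           seed = NULL) {
  stopifnot(n_bins >= 8L, block_contrast > 0, base > 0,
            bad_column_fraction >= 0, bad_column_fraction < 1)
  if (length(levels)) {
    for (l in seq_along(levels)) {
      b <- levels[[l]]
      if (any(b < 1L | b >= n_bins) || is.unsorted(b, strictly = TRUE))
        stop("boundaries must be strictly increasing within 1..n_bins-1")
      if (l > 1L && !all(levels[[l - 1L]] %in% b))
        stop("boundary sets must be nested across levels")
    }
  }
  structure(list(n_bins = as.integer(n_bins), levels = levels,
                 block_contrast = block_contrast,
                 distance_decay_exponent = distance_decay_exponent,
                 base = base, bad_column_fraction = bad_column_fraction,
                 seed = seed),
            class = "synthetic_spec")
}

boundaries_to_partition <- function(bounds, n) {
  bounds <- as.integer(bounds)
  cbind(start_bin = c(1L, bounds + 1L), end_bin = c(bounds, n))
}

#' Generate a synthetic contact matrix with planted hierarchy
#'
#' Expected counts follow
#' `E_ij = base * max(|i - j|, 1)^(-alpha) * contrast^depth(i, j)` where
#' `depth(i, j)` counts the hierarchy levels at which bins i and j share
#' a domain; observed counts are Poisson draws of the upper triangle,
#' mirrored to keep the matrix exactly symmetric. A random subset of
#' columns is zeroed to emulate bad columns.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `matrix` (a `ContactMatrix`), `truth` (list of
#'   planted bin partitions, one per level), `truth_boundaries` (the
#'   boundary sets) and `bad_bins` (zeroed columns).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_bins
  idx <- seq_len(n)
  dist_ij <- abs(outer(idx, idx, "-"))
  E <- spec$base * pmax(dist_ij, 1)^(-spec$distance_decay_exponent)
  for (bounds in spec$levels) {
    lab <- findInterval(idx - 1L, bounds) # domain id at this level
    same <- outer(lab, lab, "==")
    E <- E * ifelse(same, spec$block_contrast, 1)
  }
  obs <- matrix(0, n, n)
  up <- upper.tri(obs, diag = TRUE)
  obs[up] <- stats::rpois(sum(up), E[up])
  obs <- obs + t(obs) - diag(diag(obs))
  n_bad <- floor(spec$bad_column_fraction * n)
  bad <- if (n_bad > 0L) sort(sample.int(n, n_bad)) else integer(0)
  if (length(bad)) {
    obs[bad, ] <- 0
    obs[, bad] <- 0
  }
  truth <- lapply(spec$levels, boundaries_to_partition, n = n)
  list(matrix = contact_matrix(obs, chrom = "chrSim", start_bp = 0L,
                               resolution = 1L),
       truth = truth, truth_boundaries = spec$levels, bad_bins = bad)
}

#' Generate a peak set matched to planted boundaries
#'
#' Each planted boundary receives a peak with probability `hit_rate`
#' (centered on the boundary); background peaks appear independently in
#' each 5-kb slot of the region with probability `background_rate`,
#' uniformly placed within the slot.
#'
#' @param boundaries_bp planted boundary positions (bp).
#' @param region_start,region_end region span (bp).
#' @param hit_rate per-boundary peak probability in \[0, 1\].
#' @param background_rate per-5-kb-slot background peak probability.
#' @param peak_width peak width in bp (default 500).
#' @param seed optional integer seed.
#' @return peak data.frame (`chrom`, `start`, `end`), BED semantics.
#' @export
generate_peaks <- function(boundaries_bp, region_start, region_end,
                           hit_rate = 1, background_rate = 0,
                           peak_width = 500, seed = NULL) {
  stopifnot(hit_rate >= 0, hit_rate <= 1,
            background_rate >= 0, background_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  hits <- boundaries_bp[stats::runif(length(boundaries_bp)) < hit_rate]
  starts <- hits - peak_width / 2
  slot_starts <- seq(region_start, region_end - 1, by = 5000)
  bg_slots <- slot_starts[stats::runif(length(slot_starts)) < background_rate]
  if (length(bg_slots)) {
    bg <- bg_slots + stats::runif(length(bg_slots)) *
      pmax(0, 5000 - peak_width)
    starts <- c(starts, bg)
  }
  starts <- sort(pmax(region_start, pmin(starts, region_end - peak_width)))
  data.frame(chrom = rep("chrSim", length(starts)), start = starts,
             end = starts + peak_width)
}

#' Generate active/repressed signal tracks aligned to TADs
#'
#' Alternating TADs are assigned the active or repressed state; the
#' repressive track is high (lognormal around `high`) in repressed TADs
#' and low (around `low`) elsewhere, and vice versa for the active
#' track. Used to exercise the TAD-body state test with known truth.
#'
#' @param tads domain set (bp).
#' @param bin_size track bin size (bp).
#' @param high,low lognormal medians of the enriched and depleted state.
#' @param noise_sd lognormal sigma.
#' @param seed optional integer seed.
#' @return list with `repressive` and `active` `signal_track`s and the
#'   per-TAD `state` vector (`"repressed"`/`"active"`).
#' @export
generate_signal_tracks <- function(tads, bin_size, high = 10, low = 1,
                                   noise_sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tads <- validate_domain_set(tads, "tads")
  region <- c(tads$start[1], tads$end[nrow(tads)])
  n_bins <- ceiling((region[2] - region[1]) / bin_size)
  mids <- region[1] + (seq_len(n_bins) - 0.5) * bin_size
  tad_of_bin <- findInterval(mids, tads$start)
  state <- rep(c("repressed", "active"), length.out = nrow(tads))
  rep_med <- ifelse(state[tad_of_bin] == "repressed", high, low)
  act_med <- ifelse(state[tad_of_bin] == "active", high, low)
  ln <- function(med) med * exp(stats::rnorm(n_bins, 0, noise_sd))
  list(repressive = signal_track(ln(rep_med), bin_size, region[1]),
       active = signal_track(ln(act_med), bin_size, region[1]),
       state = state)
}
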