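# Biological-benchmark metrics: ChIP-seq peak profiles around TAD
# boundaries, boundary fold change and occupancy, replicate
# consensus/union, and the TAD-body active/repressed state test.

peaks_to_iranges <- function(peaks) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("start", "end") %in% names(peaks)))
  # BED half-open -> 1-based closed
  IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
}

iranges_to_peaks <- function(ir, chrom = "chrUnknown") {
  data.frame(chrom = rep(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir))
}

#' Peak profile around TAD boundaries (SPP/HMP)
#'
#' Average number of ChIP-seq peaks per offset slot across all
#' boundaries: the window spans `half_window` on each side of every
#' boundary, divided into `step`-sized slots; a peak counts for a slot
#' when it overlaps it by at least one bp. With the defaults this is the
#' structural-protein (or histone-mark) profile: 5 kb slots in a 1 Mb
#' window.
#'
#' @param boundaries numeric vector of boundary positions (bp).
#' @param peaks data.frame with `start`/`end` columns (BED, bp).
#' @param half_window half window size in bp (default 5e5).
#' @param step slot size in bp (default 5000).
#' @return numeric vector of mean peak counts per slot, ordered from
#'   -half_window to +half_window; names give the slot start offsets.
#'   The slot whose offset range is `[0, step)` contains the boundary.
#'   Attributes `step` and `half_window` are attached.
#' @export
spp_profile <- function(boundaries, peaks, half_window = 5e5, step = 5000) {
  if (length(boundaries) == 0L) stop("no boundaries given")
  n_slots <- as.integer(2 * half_window / step)
  offsets <- seq(-half_window, by = step, length.out = n_slots)
  slot_start <- rep(boundaries, each = n_slots) + offsets
  ir_slots <- IRanges::IRanges(start = slot_start + 1, end = slot_start + step)
  counts <- IRanges::countOverlaps(ir_slots, peaks_to_iranges(peaks))
  prof <- rowMeans(matrix(counts, nrow = n_slots))
  names(prof) <- offsets
  attr(prof, "step") <- step
  attr(prof, "half_window") <- half_window
  prof
}

#' Boundary fold change of a peak profile
#'
#' Ratio of the mean profile in the central slots (the boundary slot
#' plus/minus `center_halfwidth` slots) over the mean in two background
#' windows of `bg_width` bp placed `bg_offset` bp away on both flanks,
#' minus one, so that no enrichment maps to 0.
#'
#' @param profile output of [spp_profile()].
#' @param center_halfwidth halfwidth of the central window in slots
#'   (default 1).
#' @param bg_offset distance from the boundary to the background window
#'   (bp, default 4e5).
#' @param bg_width background window width (bp, default 1e5).
#' @return fold change minus one; undefined (condition
#'   `hictad_undefined`) when the background is zero.
#' @export
spp_fold_change <- function(profile, center_halfwidth = 1L,
                            bg_offset = 4e5, bg_width = 1e5) {
  step <- attr(profile, "step"); hw <- attr(profile, "half_window")
  if (is.null(step) || is.null(hw))
    stop("profile must come from spp_profile()")
  off <- as.numeric(names(profile))
  center_idx <- which(off >= -center_halfwidth * step &
                      off < (center_halfwidth + 1) * step)
  bg_idx <- which((off >= bg_offset & off < bg_offset + bg_width) |
                  (off >= -bg_offset - bg_width & off < -bg_offset))
  bg <- mean(profile[bg_idx])
  if (bg == 0) cond_undefined("zero background in fold-change computation")
  mean(profile[center_idx]) / bg - 1
}

#' Boundary occupancy ratio
#'
#' Fraction of boundaries harboring at least one peak within `tol_bins`
#' matrix-resolution bins.
#'
#' @param boundaries numeric vector of boundary positions (bp).
#' @param peaks data.frame with `start`/`end` (BED, bp).
#' @param tol_bins tolerance in matrix bins (default 1).
#' @param resolution matrix bin size (bp).
#' @return fraction in \[0, 1\].
#' @export
boundary_occupancy <- function(boundaries, peaks, tol_bins = 1L,
                               resolution) {
  if (length(boundaries) == 0L) stop("no boundaries given")
  tol <- tol_bins * resolution
  win <- IRanges::IRanges(start = boundaries - tol + 1, end = boundaries + tol)
  hit <- IRanges::countOverlaps(win, peaks_to_iranges(peaks)) > 0
  mean(hit)
}

#' Consensus and union of replicate peak sets
#'
#' The union merges intervals present in any replicate; the consensus
#' keeps only positions covered by every replicate.
#'
#' @param peaksets list of peak data.frames (`start`/`end`, BED bp).
#' @param chrom chromosome label for the output.
#' @return list with `consensus` and `union` peak data.frames.
#' @export
consensus_and_union <- function(peaksets, chrom = "chrUnknown") {
  stopifnot(length(peaksets) >= 1L)
  irs <- lapply(peaksets, peaks_to_iranges)
  un <- IRanges::reduce(do.call(c, irs))
  cons <- Reduce(IRanges::intersect, irs)
  list(consensus = iranges_to_peaks(cons, chrom),
       union = iranges_to_peaks(un, chrom))
}

#' Per-bin signal track
#'
#' @param values numeric vector, one value per bin (fold change over
#'   control); NA allowed.
#' @param bin_size bin size in bp.
#' @param start_bp genomic start of the first bin.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, start_bp = 0) {
  structure(list(values = as.numeric(values),
                 bin_size = as.numeric(bin_size),
                 start_bp = as.numeric(start_bp)),
            class = "signal_track")
}

# Mean of track values whose bin midpoints fall into each [s, e) window.
coarse_grain_track <- function(track, starts, ends) {
  mid <- track$start_bp + (seq_along(track$values) - 0.5) * track$bin_size
  vapply(seq_along(starts), function(i) {
    v <- track$values[mid >= starts[i] & mid < ends[i]]
    if (length(v) == 0L) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Active/repressed state test of TAD bodies
#'
#' Both signal tracks are coarse-grained into bins spanning a fixed
#' fraction (default 10%) of the mean TAD size; in each coarse bin the
#' log10 ratio of the repressive over the active mean signal is taken
#' (with a pseudocount equal to the track-wide first percentile of
#' positive values). A per-bin empirical two-sided p-value is computed
#' with a shuffle test, the Benjamini-Hochberg step-up is applied to the
#' bins of each TAD, and the TAD's FDR is the minimum adjusted p-value.
#' The reported statistic is the fraction of TADs with FDR below `fdr`.
#'
#' Two null models are available. `"label_swap"` (default) shuffles,
#' within each coarse bin, which of the two tracks each constituent fine
#' track bin belongs to (a paired two-sample permutation of the bin's
#' log ratio); it requires the tracks to be binned finer than the coarse
#' grid and yields independent per-bin p-values that are uniform when
#' the two signals are exchangeable. `"region_shuffle"` permutes the
#' coarse log-ratio values across the region and compares magnitudes;
#' it only flags bins more extreme than the region's typical ratio.
#'
#' @param tads domain set (bp, `start`/`end` columns).
#' @param repressive,active `signal_track` objects covering the region
#'   (e.g. H3K27me3 and H3K36me3 fold change over control).
#' @param n_shuffle number of shuffles (default 1000).
#' @param fdr FDR threshold (default 0.1).
#' @param coarse_frac coarse bin size as a fraction of mean TAD size
#'   (default 0.1).
#' @param null_model `"label_swap"` (default) or `"region_shuffle"`,
#'   see Details.
#' @param seed optional integer seed.
#' @return list: `fraction` (TADs with FDR < `fdr`), `tad_fdr`,
#'   `log_ratio`, `pvalues`, `coarse_bin`.
#' @export
tad_state_test <- function(tads, repressive, active, n_shuffle = 1000L,
                           fdr = 0.1, coarse_frac = 0.1,
                           null_model = c("label_swap", "region_shuffle"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  null_model <- match.arg(null_model)
  tads <- validate_domain_set(tads, "tads")
  stopifnot(inherits(repressive, "signal_track"),
            inherits(active, "signal_track"))
  if (n_shuffle < 1L) stop("n_shuffle must be >= 1")
  mean_size <- mean(tads$end - tads$start)
  cb <- coarse_frac * mean_size
  region <- c(tads$start[1], tads$end[nrow(tads)])
  starts <- seq(region[1], region[2] - cb / 2, by = cb)
  ends <- pmin(starts + cb, region[2])
  nb <- length(starts)
  eps_of <- function(tr) {
    pos <- tr$values[!is.na(tr$values) & tr$values > 0]
    if (length(pos) == 0L) 1e-6 else stats::quantile(pos, 0.01, names = FALSE)
  }
  eps_r <- eps_of(repressive); eps_a <- eps_of(active)
  rep_v <- coarse_grain_track(repressive, starts, ends)
  act_v <- coarse_grain_track(active, starts, ends)
  ratio <- log10((rep_v + eps_r) / (act_v + eps_a))
  pv <- rep(NA_real_, nb)
  if (null_model == "label_swap") {
    fine_vals <- function(tr, i) {
      mid <- tr$start_bp + (seq_along(tr$values) - 0.5) * tr$bin_size
      v <- tr$values[mid >= starts[i] & mid < ends[i]]
      v[!is.na(v)]
    }
    for (i in seq_len(nb)) {
      r <- fine_vals(repressive, i); a <- fine_vals(active, i)
      m <- min(length(r), length(a))
      if (m < 2L || !is.finite(ratio[i])) next
      r <- r[seq_len(m)]; a <- a[seq_len(m)]
      obs <- abs(log10((mean(r) + eps_r) / (mean(a) + eps_a)))
      swap <- matrix(stats::runif(n_shuffle * m) < 0.5, n_shuffle, m)
      rm_ <- sweep(swap, 2, a, "*") + sweep(!swap, 2, r, "*")
      am_ <- sweep(swap, 2, r, "*") + sweep(!swap, 2, a, "*")
      null_t <- abs(log10((rowMeans(rm_) + eps_r) /
                          (rowMeans(am_) + eps_a)))
      pv[i] <- (sum(null_t >= obs - 1e-12) + 1) / (n_shuffle + 1)
    }
  } else {
    ok <- which(is.finite(ratio))
    if (length(ok) < 2L) stop("too few informative coarse bins")
    obs <- abs(ratio[ok])
    exceed <- integer(length(ok))
    for (s in seq_len(n_shuffle)) {
      perm <- obs[sample.int(length(ok))]
      exceed <- exceed + (perm >= obs)
    }
    pv[ok] <- (exceed + 1) / (n_shuffle + 1)
  }
  mids <- (starts + ends) / 2
  tad_of_bin <- findInterval(mids, tads$start)
  tad_fdr <- vapply(seq_len(nrow(tads)), function(t) {
    p <- pv[tad_of_bin == t & !is.na(pv)]
    if (length(p) == 0L) return(NA_real_)
    min(stats::p.adjust(p, method = "BH"))
  }, numeric(1))
  list(fraction = mean(tad_fdr < fdr, na.rm = TRUE),
       tad_fdr = tad_fdr, log_ratio = ratio, pvalues = pv,
       coarse_bin = cb)
}
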