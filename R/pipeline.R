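# End-to-end orchestration: filtering -> denoising -> constrained
# clustering -> level selection.

#' Call the TAD hierarchy of a contact matrix
#'
#' Runs the full pipeline on a raw `ContactMatrix`: bad-column
#' detection, optional centromere split, bad-bin removal, PCC/PCA
#' denoising, CONISS clustering and broken-stick/CH level selection.
#'
#' @param m a `ContactMatrix` (e.g. from [read_contact_matrix()]).
#' @param percentile bad-column percentile threshold (default 1).
#' @param n_pc_max maximum retained principal components (default 200).
#' @param min_tads minimum domain count for a level to compete (default
#'   2).
#' @param centromere_split split the matrix at the longest all-zero
#'   column run and process each arm separately (default FALSE).
#' @param first_crossing broken-stick stopping rule, see
#'   [broken_stick_max_level()].
#' @return a `tad_hierarchy`, or when `centromere_split = TRUE` a list
#'   with elements `p_arm` and `q_arm`.
#' @export
call_tads <- function(m, percentile = 1, n_pc_max = 200L, min_tads = 2L,
                      centromere_split = FALSE, first_crossing = TRUE) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (n_bins(m) > 15000L && !centromere_split)
    warning("matrix exceeds 15000 bins; consider centromere_split = TRUE")
  one_arm <- function(arm) {
    arm <- detect_bad_columns(arm, percentile = percentile)
    f <- drop_masked(arm)
    tad_hierarchy(f$matrix, bm = f$bin_map, n_pc_max = n_pc_max,
                  min_tads = min_tads, first_crossing = first_crossing)
  }
  if (centromere_split) {
    arms <- split_at_centromere(m)
    lapply(arms, function(a) if (is.null(a)) NULL else one_arm(a))
  } else {
    one_arm(m)
  }
}
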