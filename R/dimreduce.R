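# Denoising transform (Pearson correlation matrix), PCA, distance matrices.

#' Pearson-correlation transform of a contact matrix
#'
#' Replaces the filtered interaction matrix by its column-column Pearson
#' correlation coefficient (PCC) matrix, the standard denoising step
#' before PCA on Hi-C maps. By symmetry of the input, rows and columns
#' give the same result.
#'
#' @param m a filtered `ContactMatrix` (>= 4 bins, no masked bins
#'   remaining) or a plain numeric matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_transform <- function(m) {
  vals <- if (inherits(m, "ContactMatrix")) m$values else m
  stopifnot(is.matrix(vals), nrow(vals) == ncol(vals))
  if (nrow(vals) < 4L) stop("need at least 4 bins")
  v <- apply(vals, 2, stats::var)
  if (any(v == 0))
    stop(sprintf("zero-variance column(s): %s (should have been masked)",
                 paste(which(v == 0), collapse = ", ")))
  pcc <- stats::cor(vals)
  diag(pcc) <- 1
  pcc
}

#' Principal component analysis of the PCC matrix
#'
#' Rows of the (symmetric) correlation matrix are treated as
#' observations; columns are mean-centered but not rescaled, matching the
#' `prcomp` default. Components with negligible variance (below
#' `rank_tol` relative to the leading one) are discarded, so the number
#' of available components equals the numerical rank.
#'
#' @param pcc square numeric matrix with finite entries.
#' @param n_pc_max maximum number of components to retain (default 200).
#' @param rank_tol relative standard-deviation cutoff defining numerical
#'   rank.
#' @return an object of class `pc_embedding` with fields `scores`
#'   (n x n_pc), `explained_variance` (fractions, all components) and
#'   `n_pc` (retained count).
#' @export
pca_reduce <- function(pcc, n_pc_max = 200L, rank_tol = 1e-8) {
  stopifnot(is.matrix(pcc), nrow(pcc) == ncol(pcc))
  if (!all(is.finite(pcc))) stop("non-finite entries in PCC matrix")
  p <- stats::prcomp(pcc, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  rank <- sum(p$sdev > rank_tol * p$sdev[1])
  keep <- min(n_pc_max, rank, ncol(p$x))
  structure(list(scores = p$x[, seq_len(keep), drop = FALSE],
                 explained_variance = ev,
                 n_pc = keep),
            class = "pc_embedding")
}

#' @export
print.pc_embedding <- function(x, ...) {
  cat(sprintf("pc_embedding: %d observations, %d components (%.1f%% var)\n",
              nrow(x$scores), x$n_pc,
              100 * sum(x$explained_variance[seq_len(x$n_pc)])))
  invisible(x)
}

#' Euclidean distance matrix over the first n_pc components
#'
#' @param e a `pc_embedding`.
#' @param n_pc number of leading components to use.
#' @return dense symmetric distance matrix.
#' @export
euclidean_distance_matrix <- function(e, n_pc) {
  stopifnot(inherits(e, "pc_embedding"))
  if (n_pc < 1L || n_pc > e$n_pc)
    stop(sprintf("n_pc must lie in [1, %d]", e$n_pc))
  as.matrix(stats::dist(e$scores[, seq_len(n_pc), drop = FALSE]))
}
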