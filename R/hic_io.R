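# Reading, validating and filtering dense intra-chromosomal contact matrices.

#' Contact matrix constructor
#'
#' Builds a `ContactMatrix`: a dense, symmetric, non-negative N x N
#' interaction matrix with bin metadata and a bad-column mask.
#'
#' @param values numeric N x N matrix of interaction counts (raw or
#'   normalized). Must be symmetric within `sym_tol` (relative to the
#'   largest absolute entry); it is symmetrized by averaging with its
#'   transpose after validation. `NA` entries are allowed and are treated
#'   as zero wherever cumulative sums are needed.
#' @param chrom chromosome label.
#' @param start_bp genomic start (bp) of the first bin, 0-based.
#' @param resolution bin size in bp.
#' @param bad_mask logical vector, `TRUE` marks an excluded bin. Defaults
#'   to all `FALSE`.
#' @param sym_tol relative symmetry tolerance (default `1e-6`).
#' @return an object of class `ContactMatrix`.
#' @export
contact_matrix <- function(values, chrom = "chrUnknown", start_bp = 0L,
                           resolution = 1L, bad_mask = NULL,
                           sym_tol = 1e-6) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop(sprintf("matrix is not square: %d rows, %d columns",
                 nrow(values), ncol(values)), call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("negative interaction counts are not allowed")
  n <- nrow(values)
  asym <- abs(values - t(values))
  asym[is.na(asym)] <- 0
  scale <- max(abs(values), 1, na.rm = TRUE)
  if (any(asym > sym_tol * scale)) {
    worst <- arrayInd(which.max(asym), dim(asym))
    stop(sprintf(
      "matrix is not symmetric within tolerance: worst cell (%d,%d): %g vs %g",
      worst[1], worst[2], values[worst[1], worst[2]],
      values[worst[2], worst[1]]), call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, n)
  stopifnot(is.logical(bad_mask), length(bad_mask) == n)
  structure(
    list(chrom = as.character(chrom), start_bp = as.integer(start_bp),
         resolution = as.integer(resolution), values = values,
         bad_mask = bad_mask),
    class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s:%d- (%d bins @ %d bp, %d masked)\n",
              x$chrom, x$start_bp, n_bins(x), x$resolution,
              sum(x$bad_mask)))
  invisible(x)
}

#' Number of bins of a ContactMatrix
#' @param m a `ContactMatrix`.
#' @export
n_bins <- function(m) nrow(m$values)

#' Read a dense contact matrix from a tab-separated file
#'
#' Reads a whitespace/tab-separated dense square text matrix. A header row
#' and/or a leading row-name column are auto-detected (any non-numeric
#' first row/column is dropped). Cells must be numeric, `NA` or `NaN`.
#'
#' @param path path to the matrix file.
#' @inheritParams contact_matrix
#' @return a `ContactMatrix` with all bins unmasked.
#' @export
read_contact_matrix <- function(path, chrom = "chrUnknown", start_bp = 0L,
                                resolution = 1L, sym_tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = FALSE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = c("NA", "NaN"))
  if (nrow(dt) == 0L) stop("empty matrix file")
  is_num <- function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || !anyNA(suppressWarnings(as.numeric(x)))
  }
  # header row/column: mostly non-numeric labels (a lone bad cell in the
  # data must stay put so it can be reported as a format error)
  frac_nonnum <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(0)
    mean(is.na(suppressWarnings(as.numeric(x))))
  }
  if (nrow(dt) > 1L && frac_nonnum(unlist(dt[1, ], use.names = FALSE)) > 0.5)
    dt <- dt[-1, , drop = FALSE]
  if (ncol(dt) > 1L && frac_nonnum(dt[[1]]) > 0.5)
    dt <- dt[, -1, drop = FALSE]
  bad_cells <- !vapply(dt, is_num, logical(1))
  if (any(bad_cells))
    stop(sprintf("non-numeric cells in column(s): %s",
                 paste(which(bad_cells), collapse = ", ")))
  vals <- vapply(dt, function(x) suppressWarnings(as.numeric(x)),
                 numeric(nrow(dt)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(dt))
  if (nrow(vals) != ncol(vals))
    stop(sprintf("matrix is not square: %d rows, %d columns",
                 nrow(vals), ncol(vals)), call. = FALSE)
  dimnames(vals) <- NULL
  contact_matrix(vals, chrom = chrom, start_bp = start_bp,
                 resolution = resolution, sym_tol = sym_tol)
}

#' Write a ContactMatrix to a tab-separated file
#' @param m a `ContactMatrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(m, path) {
  utils::write.table(m$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag low-quality (bad) columns
#'
#' Marks bins as excluded if (a) the diagonal entry is zero or missing, or
#' (b) the cumulative interactions of the column fall strictly below the
#' given percentile of all column sums. `NA` entries count as zero in the
#' sums. The percentile uses linear interpolation (`stats::quantile`
#' type 7) and is computed over all columns, including prospective bad
#' ones; set `over_all_columns = FALSE` to exclude zero-diagonal columns
#' from the reference distribution first.
#'
#' @param m a `ContactMatrix`.
#' @param percentile percentile threshold in \[0, 100\] (default 1).
#' @param over_all_columns compute the percentile over all column sums
#'   (default) or only over columns passing the diagonal rule.
#' @return `m` with `bad_mask` replaced; values untouched.
#' @export
detect_bad_columns <- function(m, percentile = 1, over_all_columns = TRUE) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (!is.numeric(percentile) || percentile < 0 || percentile > 100)
    stop("`percentile` must lie in [0, 100]")
  d <- diag(m$values)
  diag_bad <- is.na(d) | d == 0
  csums <- colSums(m$values, na.rm = TRUE)
  ref <- if (over_all_columns) csums else csums[!diag_bad]
  thr <- stats::quantile(ref, probs = percentile / 100, names = FALSE,
                         type = 7)
  m$bad_mask <- diag_bad | (csums < thr)
  m
}

#' Split a whole-chromosome matrix at the centromere
#'
#' The centromere is taken to be the longest contiguous stretch of
#' all-zero columns; ties break to the leftmost such run. Returns the two
#' flanking arm submatrices with adjusted genomic starts.
#'
#' @param m a `ContactMatrix` containing at least one all-zero column.
#' @return a list with elements `p_arm` and `q_arm` (`ContactMatrix`es).
#' @export
split_at_centromere <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  zero_col <- colSums(abs(m$values), na.rm = TRUE) == 0
  if (!any(zero_col))
    stop(paste("no all-zero column found; process the matrix whole",
               "(no centromere split needed)"))
  r <- rle(zero_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zi <- which(r$values)
  best <- zi[which.max(r$lengths[zi])]    # which.max = leftmost on ties
  run <- c(starts[best], ends[best])
  take <- function(idx, off_bins) {
    if (length(idx) == 0L) return(NULL)
    contact_matrix(m$values[idx, idx, drop = FALSE], chrom = m$chrom,
                   start_bp = m$start_bp + off_bins * m$resolution,
                   resolution = m$resolution,
                   bad_mask = m$bad_mask[idx])
  }
  list(p_arm = take(seq_len(run[1] - 1L), 0L),
       q_arm = take(seq(run[2] + 1L, length.out = n_bins(m) - run[2]),
                    run[2]))
}

#' Drop masked bins
#'
#' Restricts the matrix to unmasked rows/columns and returns the reduced
#' matrix together with a `bin_map` recording the filtered-to-original
#' index correspondence. Remaining `NA` entries are set to zero so that
#' downstream correlation/PCA steps receive complete data.
#'
#' @param m a `ContactMatrix` with `bad_mask` computed.
#' @return a list: `matrix` (filtered `ContactMatrix`), `bin_map` (see
#'   [bin_map()]), `n_original` (bin count before filtering).
#' @export
drop_masked <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  keep <- which(!m$bad_mask)
  if (length(keep) < 4L)
    stop("fewer than 4 unmasked bins: hierarchy undefined")
  vals <- m$values[keep, keep, drop = FALSE]
  vals[is.na(vals)] <- 0
  sub <- contact_matrix(vals, chrom = m$chrom, start_bp = m$start_bp,
                        resolution = m$resolution)
  list(matrix = sub, bin_map = bin_map(keep, n_bins(m)),
       n_original = n_bins(m))
}

#' Filtered/original bin index map
#'
#' @param kept_to_original strictly increasing integer vector: filtered
#'   bin index (1-based) -> original bin index (1-based).
#' @param n_original number of bins before filtering.
#' @return an object of class `bin_map` with fields `kept_to_original`
#'   and `original_to_kept` (NA where the original bin was masked).
#' @export
bin_map <- function(kept_to_original, n_original) {
  kept_to_original <- as.integer(kept_to_original)
  if (is.unsorted(kept_to_original, strictly = TRUE))
    stop("kept_to_original must be strictly increasing")
  inv <- rep(NA_integer_, n_original)
  inv[kept_to_original] <- seq_along(kept_to_original)
  structure(list(kept_to_original = kept_to_original,
                 original_to_kept = inv,
                 n_original = as.integer(n_original)),
            class = "bin_map")
}
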