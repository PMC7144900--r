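# Result writers and BED-like partition readers. All genomic output is
# 0-based half-open (BED).

#' Write all hierarchy levels as a BED-like file
#'
#' Columns: chrom, start, end, level, domain id (within level), CH index
#' of the level.
#'
#' @param h a `tad_hierarchy`.
#' @param path output path.
#' @export
write_hierarchy_bed <- function(h, path) {
  stopifnot(inherits(h, "tad_hierarchy"))
  if (h$no_hierarchy) stop("no hierarchy to write")
  rows <- lapply(h$levels, function(p) {
    bp <- partition_to_bp(p, h$chrom, h$start_bp, h$resolution)
    bp$level <- attr(p, "level")
    bp$domain <- seq_len(nrow(bp))
    bp$ch <- attr(p, "ch")
    bp
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the per-level hierarchy summary (TSV)
#'
#' @param h a `tad_hierarchy`.
#' @param path output path.
#' @export
write_hierarchy_summary <- function(h, path) {
  stopifnot(inherits(h, "tad_hierarchy"))
  if (h$no_hierarchy) {
    df <- data.frame(level = integer(0), n_tads = integer(0),
                     ch = numeric(0), optimal = logical(0))
  } else {
    lv <- seq_len(h$max_level)
    df <- data.frame(level = lv, n_tads = lv + 1L,
                     ch = vapply(h$levels, attr, numeric(1), "ch"),
                     optimal = lv == h$optimal_level)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Serialize a hierarchy to JSON
#'
#' @param h a `tad_hierarchy`.
#' @param path output path.
#' @export
write_hierarchy_json <- function(h, path) {
  stopifnot(inherits(h, "tad_hierarchy"))
  levels <- lapply(h$levels, function(p) {
    bp <- partition_to_bp(p, h$chrom, h$start_bp, h$resolution)
    list(level = attr(p, "level"), ch = attr(p, "ch"),
         domains = bp[, c("start", "end")])
  })
  obj <- list(chrom = h$chrom, start_bp = h$start_bp,
              resolution = h$resolution,
              n_bins_original = h$n_bins_original,
              n_bins_filtered = h$n_bins_filtered,
              no_hierarchy = h$no_hierarchy,
              support = h$support, stable = h$stable,
              n_pc_opt = h$n_pc_opt, max_level = h$max_level,
              optimal_level = h$optimal_level,
              n_tads_opt = h$n_tads_opt, levels = levels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a BED-like partition file
#'
#' Accepts the files written by [write_hierarchy_bed()] (with or without
#' a header) or any 3+-column BED. When a `level` column is present and
#' `level` is given, only that level is returned.
#'
#' @param path input path.
#' @param level optional level to extract.
#' @return data.frame with `chrom`, `start`, `end` (plus `level` when
#'   present), sorted by start.
#' @export
read_partition_bed <- function(path, level = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.numeric(df[[2]])) {  # header row present
    colnames(df) <- as.character(unlist(df[1, ]))
    df <- df[-1, , drop = FALSE]
    for (j in 2:ncol(df))
      df[[j]] <- suppressWarnings(as.numeric(df[[j]]))
  } else {
    colnames(df)[1:3] <- c("chrom", "start", "end")
    if (ncol(df) >= 4 && is.numeric(df[[4]])) colnames(df)[4] <- "level"
  }
  if (!is.null(level)) {
    if (!"level" %in% names(df)) stop("no `level` column in file")
    df <- df[df$level == level, , drop = FALSE]
    if (nrow(df) == 0L) stop(sprintf("level %s not present", level))
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
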