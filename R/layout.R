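#' Genome layout: ordered chromosomes cut into fixed-size windows
#'
#' A layout fixes the chromosome order, chromosome lengths and the window
#' size used by every windowed statistic. Windows are half-open, 0-based
#' `[start, start + window_size)` intervals (BED convention); the last window
#' of a chromosome may be short. Input site positions are 1-based (VCF
#' convention).
#'
#' @param chrom character vector of chromosome names (order is kept and used
#'   for sorting all outputs).
#' @param length integer vector of chromosome lengths in base pairs.
#' @param window_size window size in base pairs (default 100 kb).
#' @return An object of class `genome_layout`: a data frame with columns
#'   `chrom` and `length` and a `window_size` attribute.
#' @examples
#' lay <- genome_layout(c("chr1", "chr2"), c(1e6, 3e5))
#' layout_windows(lay)
#' @export
genome_layout <- function(chrom, length, window_size = 1e5) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (any(!is.finite(length)) || any(length <= 0)) stop("chromosome lengths must be > 0")
  if (!is.finite(window_size) || window_size <= 0) stop("window_size must be > 0")
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(out, "window_size") <- window_size
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.0f bp, window size %.0f bp\n",
              nrow(x), sum(x$length), attr(x, "window_size")))
  invisible(x)
}

#' Window size of a layout
#' @param layout a [genome_layout()].
#' @return Window size in base pairs.
#' @export
window_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  attr(layout, "window_size")
}

#' Read / write a genome layout
#'
#' Two-column TSV (`chrom`, `length`); chromosome order is taken from the
#' file, not sorted.
#'
#' @param path file path.
#' @param window_size window size passed to [genome_layout()].
#' @return [read_layout()] returns a `genome_layout`.
#' @export
read_layout <- function(path, window_size = 1e5) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(df))) {
    stop("layout file must have columns 'chrom' and 'length'")
  }
  genome_layout(df$chrom, df$length, window_size = window_size)
}

#' @param layout a `genome_layout` to write.
#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(as.data.frame(layout)[, c("chrom", "length")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate all windows of a layout
#'
#' Windows partition every chromosome: each base pair falls in exactly one
#' window. The `window` column is the canonical window identifier
#' `"chrom:start"` used throughout the package.
#'
#' @param layout a [genome_layout()].
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `window`.
#' @export
layout_windows <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  ws <- window_size(layout)
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = ws)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + ws, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$window <- window_id(out$chrom, out$start)
  rownames(out) <- NULL
  out
}

#' Canonical window identifier
#' @param chrom chromosome name(s).
#' @param start 0-based window start(s).
#' @return Character vector `"chrom:start"`.
#' @export
window_id <- function(chrom, start) {
  paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE))
}

#' Assign 1-based positions to windows
#'
#' Position `p` (1-based) maps to the window starting at
#' `floor((p - 1) / window_size) * window_size`; position `window_size`
#' itself still belongs to the first window (half-open upper boundary).
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 1-based positions.
#' @return Character vector of window IDs.
#' @examples
#' lay <- genome_layout("chr1", 1e6)
#' assign_window(lay, "chr1", c(1, 1e5, 1e5 + 1))
#' @export
assign_window <- function(layout, chrom, pos) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  idx <- match(chrom, layout$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  if (any(pos < 1)) stop("positions are 1-based; got pos < 1")
  over <- pos > layout$length[idx]
  if (any(over)) {
    stop(sprintf("position %.0f beyond end of %s (%.0f bp)",
                 pos[which(over)[1]], chrom[which(over)[1]],
                 layout$length[idx[which(over)[1]]]))
  }
  ws <- window_size(layout)
  window_id(chrom, floor((pos - 1) / ws) * ws)
}

# Order rows of a window-keyed data frame by (layout chromosome order, start).
order_by_layout <- function(df, layout) {
  ord <- order(match(df$chrom, layout$chrom), df$start)
  df[ord, , drop = FALSE]
}
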