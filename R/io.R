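#' Read per-site allele counts for one population pair
#'
#' TSV with header `chrom, pos, ac1, n1, ac2, n2[, depth]`: 1-based position,
#' alternate-allele count and allele sample size for each population. Rows
#' are validated (`0 <= ac <= n`, `n > 0`, positions strictly increasing
#' within a chromosome) and malformed rows are reported with their line
#' number.
#'
#' @param path file path.
#' @return Data frame of validated site records with derived allele
#'   frequencies `p1 = ac1/n1` and `p2 = ac2/n2`.
#' @export
read_site_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ac1", "n1", "ac2", "n2")
  if (!all(required %in% names(df))) {
    stop("site-count file must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("empty site-count file: ", path)
    df$p1 <- numeric(0); df$p2 <- numeric(0)
    return(df)
  }
  validate_site_counts(df, file = path)
}

# Shared validation for site-count tables read from file or built in memory.
# `file` only affects error messages (line numbers include the header line).
validate_site_counts <- function(df, file = NULL) {
  where <- function(i) {
    if (is.null(file)) sprintf("row %d", i) else sprintf("%s line %d", file, i + 1L)
  }
  num_cols <- c("pos", "ac1", "n1", "ac2", "n2")
  for (col in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) stop(sprintf("malformed value in column '%s' at %s", col, where(bad[1])))
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(df$n1 <= 0 | df$n2 <= 0)
  if (length(bad)) stop("sample size n <= 0 at ", where(bad[1]))
  bad <- which(df$ac1 < 0 | df$ac2 < 0 | df$ac1 > df$n1 | df$ac2 > df$n2)
  if (length(bad)) stop("allele count outside [0, n] at ", where(bad[1]))
  disorder <- unlist(lapply(split(seq_len(nrow(df)), df$chrom), function(i) {
    i[which(diff(df$pos[i]) <= 0) + 1L]
  }), use.names = FALSE)
  if (length(disorder)) {
    stop("positions not strictly increasing within chromosome at ", where(min(disorder)))
  }
  df$p1 <- df$ac1 / df$n1
  df$p2 <- df$ac2 / df$n2
  df
}

#' Write / read a per-window statistics table
#'
#' BED-like TSV: `chrom`, 0-based `start`, `end`, then named statistic and
#' feature columns. Missing values are serialized as `NA`. Rows are written
#' in layout order (chromosome order of the layout file, then start) and
#' round-trip losslessly.
#'
#' @param stats data frame with at least `chrom`, `start`, `end`.
#' @param path file path.
#' @param layout optional [genome_layout()]; when given, rows are sorted by
#'   its chromosome order before writing.
#' @return `write_window_table` returns `path` invisibly;
#'   `read_window_table` returns the data frame with a `window` ID column.
#' @export
write_window_table <- function(stats, path, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(stats)))
  df <- as.data.frame(stats)
  df$window <- NULL
  if (!is.null(layout)) df <- order_by_layout(df, layout)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$window <- window_id(df$chrom, df$start)
  df
}

#' Read a per-window genomic feature table
#'
#' TSV keyed by (`chrom`, `start`) with feature columns such as `gc`, `ds`,
#' `gene_count`, `mean_ld`.
#'
#' @param path file path.
#' @return Data frame with a `window` ID column.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot(all(c("chrom", "start") %in% names(df)))
  df$window <- window_id(df$chrom, df$start)
  df
}

#' Read centromere intervals (BED)
#'
#' Three-column BED (`chrom`, `start`, `end`; 0-based half-open), no header.
#'
#' @param path file path.
#' @return Data frame with columns `chrom`, `start`, `end`; zero rows if the
#'   file is empty.
#' @export
read_centromeres <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) data.frame(V1 = character(), V2 = numeric(), V3 = numeric())
  )
  names(df)[1:3] <- c("chrom", "start", "end")
  df[, c("chrom", "start", "end")]
}

#' Read per-pair scalar metadata
#'
#' TSV with columns `pair`, `width_km`, `pct_hybrids`, `cytb_pdist`,
#' `auto_dist` (extra columns are kept). Ranges are validated.
#'
#' @param path file path.
#' @return Data frame, one row per population pair.
#' @export
read_pair_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot("pair" %in% names(df))
  if ("width_km" %in% names(df) && any(df$width_km < 0, na.rm = TRUE)) {
    stop("hybrid zone width must be >= 0")
  }
  if ("pct_hybrids" %in% names(df) &&
      any(df$pct_hybrids < 0 | df$pct_hybrids > 100, na.rm = TRUE)) {
    stop("percent hybrids must be in [0, 100]")
  }
  if ("cytb_pdist" %in% names(df) &&
      any(df$cytb_pdist < 0 | df$cytb_pdist > 1, na.rm = TRUE)) {
    stop("p-distance must be in [0, 1]")
  }
  df
}

#' Write / read a labelled pair matrix
#'
#' TSV with row and column labels; used for repeatability and continuum
#' distance matrices.
#'
#' @param m a [pair_matrix()] or labelled square matrix.
#' @param path file path.
#' @export
write_pair_matrix <- function(m, path) {
  df <- data.frame(pair = rownames(m), as.data.frame(unclass(m)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  pair_matrix(m, validate = FALSE)
}

#' Published cross-pair correlation matrix (worked example)
#'
#' An 8x8 matrix of correlation coefficients comparing 100 kb windowed
#' differentiation landscapes across eight avian sister population pairs, as
#' reported in a published comparative genome-scan study: Pearson
#' correlations of windowed F_ST below the diagonal and of d_XY above the
#' diagonal. d_XY entries involving the greenish warbler pair are missing
#' (its reduced-representation data failed the callable-site filter).
#'
#' @return Square numeric matrix with pair labels; `NA` where not estimated.
#' @examples
#' m <- published_pair_correlations()
#' variance_explained(m, triangle = "lower")  # F_ST worked example
#' @export
published_pair_correlations <- function() {
  path <- system.file("extdata", "published_pair_correlations.tsv", package = "repscan")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
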