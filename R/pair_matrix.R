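#' Symmetric matrix over population pairs
#'
#' Thin S3 wrapper around a labelled symmetric numeric matrix whose rows and
#' columns are population pairs (repeatability coefficients, continuum
#' distances, ...). The diagonal is undefined and ignored by all consumers.
#'
#' @param m square numeric matrix with identical row/column labels.
#' @param validate check symmetry (off-diagonal entries, `NA`-tolerant).
#' @return An object of class `pair_matrix`.
#' @export
pair_matrix <- function(m, validate = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("pair matrix must be square")
  if (is.null(rownames(m))) rownames(m) <- paste0("pair", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m))) stop("row/column labels differ")
  if (validate) {
    off <- abs(m - t(m))
    if (any(off > 1e-8, na.rm = TRUE)) stop("pair matrix is not symmetric")
  }
  class(m) <- c("pair_matrix", class(m))
  m
}

#' @export
print.pair_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("pair_matrix over %d pairs\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Vectorize the lower triangle of a pair matrix
#' @param m a square matrix.
#' @return Numeric vector of below-diagonal entries (column-major).
#' @export
lower_triangle <- function(m) {
  m <- unclass(as.matrix(m))
  m[lower.tri(m)]
}
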