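#' Mean between-group p-distance from an alignment
#'
#' Proportion of nucleotide sites that differ between two groups of aligned
#' sequences: for every cross-group sequence pair, sites where either
#' member has a gap or ambiguity code are excluded, the proportion of
#' differing sites among the compared sites is taken, and the proportions
#' are averaged over all cross-group pairs.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, a list of such, or a path to an aligned FASTA file (read
#'   with [ape::read.FASTA()]).
#' @param groupA,groupB sequence names of the two groups.
#' @return Mean p-distance (proportion in \[0, 1\]).
#' @examples
#' p_distance(c(a = "ACGT", b = "ACGA"), "a", "b")  # 0.25
#' @export
p_distance <- function(alignment, groupA, groupB) {
  seqs <- load_alignment(alignment)
  missing <- setdiff(c(groupA, groupB), names(seqs))
  if (length(missing)) stop("sequences not in alignment: ", paste(missing, collapse = ", "))
  lens <- unique(vapply(seqs, length, integer(1)))
  if (length(lens) != 1) stop("sequences are not aligned (unequal lengths)")
  ok_base <- function(x) x %in% c("a", "c", "g", "t")
  dists <- c()
  for (i in groupA) {
    for (j in groupB) {
      s1 <- seqs[[i]]; s2 <- seqs[[j]]
      comparable <- ok_base(s1) & ok_base(s2)
      if (!any(comparable)) stop("no comparable sites between ", i, " and ", j)
      dists <- c(dists, mean(s1[comparable] != s2[comparable]))
    }
  }
  mean(dists)
}

# Accept FASTA path, DNAbin, character vector or list; return list of
# lower-case per-base character vectors.
load_alignment <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    x <- ape::read.FASTA(x)
  }
  if (inherits(x, "DNAbin")) {
    return(lapply(as.character(as.list(x)), tolower))
  }
  if (is.character(x)) x <- as.list(x)
  lapply(x, function(s) {
    if (length(s) == 1) s <- strsplit(s, "")[[1]]
    tolower(s)
  })
}

#' Build a pair matrix from per-pair scalars
#'
#' Turns one scalar per population pair (hybrid zone width, percent
#' hybrids, genetic distance, divergence stage, ...) into a symmetric
#' matrix for Mantel tests. `mode = "mean"` (default) sets entry (i, j) to
#' `mean(v_i, v_j)` — small when both pairs sit at the same end of the
#' continuum, which matches a hypothesis about the joint progression of two
#' pairs; `mode = "absdiff"` uses `|v_i - v_j|`.
#'
#' @param values named numeric vector, one scalar per pair.
#' @param mode `"mean"` or `"absdiff"`.
#' @return A [pair_matrix()] with zero diagonal.
#' @export
scalar_to_matrix <- function(values, mode = c("mean", "absdiff")) {
  mode <- match.arg(mode)
  miss <- is.na(values)
  if (any(miss)) {
    warning("dropping pair(s) with missing scalar: ",
            paste(names(values)[miss], collapse = ", "))
    values <- values[!miss]
  }
  if (is.null(names(values))) names(values) <- paste0("pair", seq_along(values))
  n <- length(values)
  m <- switch(mode,
    mean = outer(values, values, function(a, b) (a + b) / 2),
    absdiff = abs(outer(values, values, `-`))
  )
  diag(m) <- 0
  dimnames(m) <- list(names(values), names(values))
  pair_matrix(m)
}

# Correlation of lower triangles under a label permutation of B.
mantel_r <- function(la, B, perm, method) {
  stats::cor(la, lower_triangle(unclass(B)[perm, perm]), method = method)
}

mantel_pvalue <- function(r_obs, r_perm, alternative) {
  switch(alternative,
    greater = (1 + sum(r_perm >= r_obs)) / (length(r_perm) + 1),
    less = (1 + sum(r_perm <= r_obs)) / (length(r_perm) + 1),
    two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (length(r_perm) + 1)
  )
}

#' Mantel test between two pair matrices
#'
#' Correlates the vectorized lower triangles of two symmetric matrices over
#' the same labels and assesses significance by jointly permuting the
#' row/column order of `B`. The Spearman rank coefficient is the default:
#' with a handful of pairs a non-parametric coefficient plus permutation
#' inference is the robust choice.
#'
#' @param A,B [pair_matrix()] objects with identical labels (dimension >= 4).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @param alternative direction of the test: `"two.sided"` (default),
#'   `"greater"` or `"less"`.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`,
#'   `alternative`.
#' @export
mantel <- function(A, B, method = c("spearman", "pearson"), n_perm = 9999,
                   seed = NULL, alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  check_conformable(A, B)
  n <- nrow(A)
  if (n < 4) stop("Mantel test needs at least 4 labels")
  if (!is.null(seed)) set.seed(seed)
  la <- lower_triangle(A)
  r_obs <- mantel_r(la, B, seq_len(n), method)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    mantel_r(la, B, sample.int(n), method)
  }, numeric(1))
  structure(list(r = r_obs, p = mantel_pvalue(r_obs, r_perm, alternative),
                 n_perm = n_perm, alternative = alternative, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  ci <- if (is.null(x$ci)) "" else sprintf(" CI=[%.2f, %.2f]", x$ci[1], x$ci[2])
  cat(sprintf("%s r=%.3f%s p=%.4g (%s, %d permutations)\n",
              if (is.null(x$control)) "Mantel" else "partial Mantel",
              x$r, ci, x$p, x$alternative, x$n_perm))
  invisible(x)
}

check_conformable <- function(...) {
  ms <- list(...)
  labs <- rownames(ms[[1]])
  for (m in ms[-1]) {
    if (!identical(rownames(m), labs)) stop("matrices have different labels")
  }
  invisible(TRUE)
}

# First-order partial correlation of x and y given z.
partial_cor <- function(x, y, z, method) {
  if (stats::sd(z) == 0) return(stats::cor(x, y, method = method))
  rxy <- stats::cor(x, y, method = method)
  rxz <- stats::cor(x, z, method = method)
  ryz <- stats::cor(y, z, method = method)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den < 1e-12) return(0)  # control fully explains x or y
  (rxy - rxz * ryz) / sqrt(den)
}

#' Partial Mantel test controlling a third matrix
#'
#' First-order partial correlation between the lower triangles of `A` and
#' `B` controlling for `C` (e.g. phylogenetic distance between the focal
#' taxa). Significance by permuting `A`'s label order; a percentile
#' bootstrap confidence interval is built by resampling labels with
#' replacement (self-pairs dropped).
#'
#' @param A,B,C conformable [pair_matrix()] objects; `C` is the control.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm permutations for the p-value (default 9999).
#' @param n_boot bootstrap resamples for the CI (default 1000; 0 skips it).
#' @param seed optional integer seed.
#' @param alternative test direction (default `"two.sided"`).
#' @param conf CI coverage (default 0.95).
#' @return `mantel_result` with fields `r`, `p`, `ci`, `control = TRUE`.
#' @export
partial_mantel <- function(A, B, C, method = c("spearman", "pearson"),
                           n_perm = 9999, n_boot = 1000, seed = NULL,
                           alternative = c("two.sided", "greater", "less"),
                           conf = 0.95) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  check_conformable(A, B, C)
  n <- nrow(A)
  if (n < 4) stop("partial Mantel test needs at least 4 labels")
  if (!is.null(seed)) set.seed(seed)
  lb <- lower_triangle(B)
  lc <- lower_triangle(C)
  if (stats::sd(lb) > 0 && stats::sd(lc) > 0 &&
      abs(stats::cor(lb, lc, method = method)) > 0.999) {
    warning("control matrix is collinear with B (|r| > 0.999)")
  }
  tri_perm <- function(M, perm) lower_triangle(unclass(M)[perm, perm])
  r_obs <- partial_cor(lower_triangle(A), lb, lc, method)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    partial_cor(tri_perm(A, sample.int(n)), lb, lc, method)
  }, numeric(1))
  ci <- NULL
  if (n_boot > 0) {
    r_boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      keep <- outer(idx, idx, `!=`)[lower.tri(diag(n))]
      if (sum(keep) < 3) return(NA_real_)
      pa <- tri_perm(A, idx)[keep]
      pb <- tri_perm(B, idx)[keep]
      pc <- tri_perm(C, idx)[keep]
      if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(NA_real_)
      partial_cor(pa, pb, pc, method)
    }, numeric(1))
    ci <- stats::quantile(r_boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  structure(list(r = r_obs, p = mantel_pvalue(r_obs, r_perm, alternative),
                 ci = ci, n_perm = n_perm, n_boot = n_boot,
                 alternative = alternative, method = method, control = TRUE),
            class = "mantel_result")
}
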