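#' Cross-pair correlation matrix of windowed differentiation
#'
#' Correlates windowed estimates between every two population pairs on the
#' harmonized window set (windows non-missing in all pairs). Pearson by
#' default so that squaring the coefficient reads as variance explained;
#' Spearman available.
#'
#' @param tables named list of window tables.
#' @param stat statistic column (`"fst"` or `"dxy"`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [pair_matrix()] of correlation coefficients (diagonal 1);
#'   attribute `n_windows` gives the common window count.
#' @export
correlate_pairs <- function(tables, stat = "fst", method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- harmonize_windows(tables, stat)
  keep <- attr(common, "pairs")
  tables <- tables[keep]
  if (length(common) < 3) stop("fewer than 3 common windows")
  vals <- vapply(tables, function(t) t[[stat]][match(common, t$window)],
                 numeric(length(common)))
  m <- stats::cor(vals, method = method)
  out <- pair_matrix(m)
  attr(out, "n_windows") <- length(common)
  attr(out, "stat") <- stat
  out
}

#' Maximum pairwise correlation and variance explained
#'
#' The strongest off-diagonal coefficient of a cross-pair correlation
#' matrix, squared and expressed as a rounded percentage — "up to X% of the
#' variation in one pair's landscape is explained by another's".
#'
#' @param m a [pair_matrix()] or square matrix (may hold two statistics in
#'   its two triangles).
#' @param triangle which entries to scan: `"all"` off-diagonal entries
#'   (default), `"lower"` or `"upper"` triangle only.
#' @return List with `max_r` and `pct_variance` (= `round(100 * max_r^2)`).
#' @export
variance_explained <- function(m, triangle = c("all", "lower", "upper")) {
  triangle <- match.arg(triangle)
  m <- unclass(as.matrix(m))
  vals <- switch(triangle,
    all   = m[row(m) != col(m)],
    lower = m[lower.tri(m)],
    upper = m[upper.tri(m)]
  )
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no non-missing off-diagonal values")
  max_r <- max(vals)
  list(max_r = max_r, pct_variance = round(100 * max_r^2))
}

#' Call outlier windows in one tail of a pair's distribution
#'
#' Outliers are windows strictly beyond the empirical `q`-quantile of the
#' pair's own distribution on the harmonized universe: above the upper
#' `1 - q` quantile (F_ST) or below the lower `q` quantile (d_XY).
#'
#' @param tbl window table with the statistic column.
#' @param stat statistic column name.
#' @param tail `"upper"` or `"lower"`.
#' @param q tail probability (default 0.05).
#' @param universe optional character vector restricting the windows
#'   considered (e.g. from [harmonize_windows()]); defaults to the table's
#'   non-missing windows.
#' @return An object of class `outlier_set`: list with `members`,
#'   `universe`, `statistic`, `tail`, `q`.
#' @export
call_outliers <- function(tbl, stat = "fst", tail = c("upper", "lower"), q = 0.05,
                          universe = NULL) {
  tail <- match.arg(tail)
  v <- stats::setNames(tbl[[stat]], tbl$window)
  if (!is.null(universe)) v <- v[names(v) %in% universe]
  v <- v[!is.na(v)]
  if (length(v) < 20) stop("need at least 20 non-missing windows to call ", q, " tails")
  if (tail == "upper") {
    thr <- stats::quantile(v, 1 - q, names = FALSE)
    members <- names(v)[v > thr]
  } else {
    thr <- stats::quantile(v, q, names = FALSE)
    members <- names(v)[v < thr]
  }
  if (length(members) == 0) warning("degenerate distribution: no outliers called")
  structure(list(statistic = stat, tail = tail, q = q, threshold = thr,
                 members = members, universe = names(v)),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set: %s %s tail q=%g, %d / %d windows\n",
              x$statistic, x$tail, x$q, length(x$members), length(x$universe)))
  invisible(x)
}

#' Hypergeometric test of outlier-window overlap between two pairs
#'
#' Under the null that each window of the shared universe (size `N`) is
#' equally likely to be an outlier, the overlap `k` between outlier sets of
#' sizes `a` and `b` is hypergeometric: expectation `E = a b / N`, variance
#' `a b (N - a)(N - b) / (N^2 (N - 1))`. Reports the z score
#' `(k - E)/sqrt(Var)` (an effect size comparable across studies) and the
#' one-sided p-value `P(X >= k)`.
#'
#' `p_method` controls the p-value flavour: `"exact"` (default) is the
#' hypergeometric tail; `"mid"` halves the mass at `k`; `"randomized"` is
#' the fuzzy p-value `P(X > k) + U * P(X = k)` which is exactly uniform
#' under the null and is the right scale for calibration studies of a
#' discrete test.
#'
#' @param A,B `outlier_set`s over the same universe.
#' @param p_method p-value flavour, see Details.
#' @return List of class `overlap_result`: `k`, `expected`, `z`, `p`,
#'   `N`, `a`, `b`.
#' @export
overlap_test <- function(A, B, p_method = c("exact", "mid", "randomized")) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(A, "outlier_set"), inherits(B, "outlier_set"))
  if (!setequal(A$universe, B$universe)) stop("outlier sets have different universes")
  N <- as.numeric(length(A$universe))
  if (N == 0) stop("empty universe")
  a <- as.numeric(length(A$members))
  b <- as.numeric(length(B$members))
  k <- length(intersect(A$members, B$members))
  E <- a * b / N
  Var <- if (N > 1) a * b * (N - a) * (N - b) / (N^2 * (N - 1)) else 0
  z <- if (Var > 0) (k - E) / sqrt(Var) else NA_real_
  # P(X >= k) with X ~ Hypergeometric(N, a, b)
  p_exact <- stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  p <- switch(p_method,
    exact = p_exact,
    mid = p_exact - 0.5 * stats::dhyper(k, a, N - a, b),
    randomized = stats::phyper(k, a, N - a, b, lower.tail = FALSE) +
      stats::runif(1) * stats::dhyper(k, a, N - a, b)
  )
  structure(list(k = k, expected = E, z = z, p = p, N = N, a = a, b = b,
                 variance_zero = Var == 0, p_method = p_method),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k=%d expected=%.2f z=%.2f p=%.3g (N=%d, a=%d, b=%d)\n",
              x$k, x$expected, x$z, x$p, x$N, x$a, x$b))
  invisible(x)
}

#' Merge adjacent outlier windows into peaks
#'
#' Collapses maximal runs of genomically adjacent outlier windows (same
#' chromosome, consecutive window indices) into peaks; no two peaks are
#' adjacent.
#'
#' @param A an `outlier_set` (window IDs `"chrom:start"`).
#' @param layout a [genome_layout()].
#' @return Data frame with columns `chrom`, `first` and `last` (window
#'   indices, 0-based), `start`, `end` (bp) and `length` (window count).
#' @export
merge_peaks <- function(A, layout) {
  ws <- window_size(layout)
  if (length(A$members) == 0) {
    return(data.frame(chrom = character(), first = integer(), last = integer(),
                      start = numeric(), end = numeric(), length = integer()))
  }
  parts <- strsplit(A$members, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  idx <- as.numeric(vapply(parts, `[`, character(1), 2)) / ws
  ord <- order(match(chrom, layout$chrom), idx)
  chrom <- chrom[ord]; idx <- idx[ord]
  new_run <- c(TRUE, chrom[-1] != chrom[-length(chrom)] | diff(idx) != 1)
  run <- cumsum(new_run)
  first <- tapply(idx, run, min)
  last <- tapply(idx, run, max)
  rchrom <- tapply(chrom, run, `[`, 1)
  out <- data.frame(chrom = as.character(rchrom), first = as.integer(first),
                    last = as.integer(last), stringsAsFactors = FALSE)
  chrlen <- layout$length[match(out$chrom, layout$chrom)]
  out$start <- out$first * ws
  out$end <- pmin((out$last + 1) * ws, chrlen)
  out$length <- out$last - out$first + 1L
  out <- out[order(match(out$chrom, layout$chrom), out$first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Uniformly place peaks of given window-lengths on a chromosome of n_win
# windows. Placements are non-overlapping and non-adjacent: peaks are
# maximal runs by construction, so a valid peak set never contains two
# adjacent peaks, and this placement distribution is exactly the
# conditional law of run locations for a uniform random outlier subset
# given its run lengths. Returns 0-based first indices aligned with
# `lengths`.
place_peaks <- function(lengths, n_win) {
  k <- length(lengths)
  if (k == 0) return(integer(0))
  M <- n_win - sum(lengths) + 1L
  if (M < k) stop("peaks cannot be placed: chromosome too small")
  perm <- sample.int(k)
  l <- lengths[perm]
  u <- sort(sample.int(M, k))             # distinct slots in compressed space
  first <- (u - 1L) + c(0L, cumsum(l))[seq_len(k)]
  first[order(perm)]
}

# Count A peaks overlapping any B peak on one chromosome, via a cumulative
# occupancy vector (0-based window indices).
count_overlap_chr <- function(firstA, lastA, firstB, lastB, n_win) {
  if (length(firstA) == 0 || length(firstB) == 0) return(0L)
  occ <- logical(n_win)
  for (j in seq_along(firstB)) occ[(firstB[j] + 1L):(lastB[j] + 1L)] <- TRUE
  cs <- c(0L, cumsum(occ))
  sum(cs[lastA + 2L] - cs[firstA + 1L] > 0L)
}

# Count peaks of A intersecting >= 1 peak of B (interval overlap in window
# index space). Peaks given as data frames with chrom/first/last.
count_intersecting <- function(A, B, n_win) {
  if (nrow(A) == 0 || nrow(B) == 0) return(0L)
  n <- 0L
  for (ch in unique(A$chrom)) {
    ia <- A$chrom == ch
    ib <- B$chrom == ch
    if (!any(ib)) next
    n <- n + count_overlap_chr(A$first[ia], A$last[ia], B$first[ib], B$last[ib],
                               n_win[[ch]])
  }
  n
}

#' Permutation test for shared differentiation peaks
#'
#' Observed statistic: number of peaks of `A` intersecting at least one
#' peak of `B` (the B-side count is also reported). The null holds the
#' number and size of peaks constant and permutes their locations: in each
#' of `n_perm` rounds, every peak of both sets is placed uniformly at
#' random on its own chromosome, non-overlapping and non-adjacent within a
#' set (peaks are maximal runs, so valid configurations never contain
#' adjacent peaks). One-sided
#' p-value with the add-one estimator `(1 + #\{perm >= obs\}) / (n_perm + 1)`;
#' `p_method = "randomized"` instead returns the fuzzy permutation p-value
#' (uniform under the null), appropriate for calibration studies.
#'
#' @param peaksA,peaksB peak tables from [merge_peaks()].
#' @param layout a [genome_layout()].
#' @param n_perm number of permutations (default 1000; must be >= 1).
#' @param seed optional integer seed.
#' @param p_method `"exact"` (add-one) or `"randomized"`.
#' @return List: `observed` (A-side), `observed_b`, `p`, `n_perm`.
#' @export
peak_overlap_permutation <- function(peaksA, peaksB, layout, n_perm = 1000,
                                     seed = NULL, p_method = c("exact", "randomized")) {
  p_method <- match.arg(p_method)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ws <- window_size(layout)
  n_win <- stats::setNames(ceiling(layout$length / ws), layout$chrom)
  bad <- setdiff(unique(c(peaksA$chrom, peaksB$chrom)), layout$chrom)
  if (length(bad)) stop("peaks on chromosomes absent from layout: ",
                        paste(bad, collapse = ", "))
  observed <- count_intersecting(peaksA, peaksB, n_win)
  observed_b <- count_intersecting(peaksB, peaksA, n_win)
  lenA <- split(as.integer(peaksA$length), peaksA$chrom)
  lenB <- split(as.integer(peaksB$length), peaksB$chrom)
  chroms <- union(names(lenA), names(lenB))
  # validate placements are feasible before permuting
  for (ch in chroms) {
    for (l in list(lenA[[ch]], lenB[[ch]])) {
      if (!is.null(l) && sum(l) + length(l) - 1 > n_win[[ch]]) {
        stop("peaks cannot be placed: chromosome ", ch, " too small")
      }
    }
  }
  perm_stat <- vapply(seq_len(n_perm), function(i) {
    tot <- 0L
    for (ch in chroms) {
      la <- lenA[[ch]]; lb <- lenB[[ch]]
      if (is.null(la) || is.null(lb)) next
      fa <- place_peaks(la, n_win[[ch]])
      fb <- place_peaks(lb, n_win[[ch]])
      tot <- tot + count_overlap_chr(fa, fa + la - 1L, fb, fb + lb - 1L, n_win[[ch]])
    }
    tot
  }, integer(1))
  p <- switch(p_method,
    exact = (1 + sum(perm_stat >= observed)) / (n_perm + 1),
    randomized = (sum(perm_stat > observed) +
                    stats::runif(1) * (1 + sum(perm_stat == observed))) / (n_perm + 1)
  )
  list(observed = observed, observed_b = observed_b, p = p, n_perm = n_perm,
       p_method = p_method)
}

#' Per-window repeatability counts
#'
#' For each window of the harmonized universe, the number of population
#' pairs in which it was called an outlier. Bounded by the number of pairs
#' contributing the statistic; kept as separate tracks for F_ST and d_XY.
#'
#' @param sets list of `outlier_set`s over a common universe.
#' @return Data frame with columns `window` and `count`; attribute
#'   `n_pairs`.
#' @export
repeatability_count <- function(sets) {
  stopifnot(length(sets) >= 1)
  universe <- sets[[1]]$universe
  for (s in sets) {
    if (!setequal(s$universe, universe)) stop("outlier sets have different universes")
  }
  count <- rowSums(vapply(sets, function(s) universe %in% s$members,
                          logical(length(universe))))
  out <- data.frame(window = universe, count = as.integer(count),
                    stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- length(sets)
  out
}

#' Multiple-testing adjustment of p-values
#'
#' Holm (default, family-wise) or Benjamini-Hochberg (FDR), via
#' [stats::p.adjust()].
#'
#' @param p numeric p-values in \[0, 1\].
#' @param method `"holm"` or `"bh"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = ifelse(method == "bh", "BH", "holm"))
}

#' All pairwise overlap tests
#'
#' Convenience wrapper running [overlap_test()] for every two outlier sets
#' and adjusting the one-sided p-values across comparisons.
#'
#' @param sets named list of `outlier_set`s over a common universe.
#' @param adjust multiple-testing method passed to [adjust_pvalues()].
#' @return Data frame, one row per pair-of-pairs: `pair1`, `pair2`, `k`,
#'   `expected`, `z`, `p`, `p_adjusted`.
#' @export
overlap_table <- function(sets, adjust = "holm") {
  stopifnot(length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("pair", seq_along(sets))
  combos <- utils::combn(names(sets), 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    r <- overlap_test(sets[[combos[1, i]]], sets[[combos[2, i]]])
    data.frame(pair1 = combos[1, i], pair2 = combos[2, i], k = r$k,
               expected = r$expected, z = r$z, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p, method = adjust)
  out
}
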