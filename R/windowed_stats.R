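#' Per-site absolute differentiation (d_XY)
#'
#' For allele frequencies `p1`, `p2` of the same allele in the two
#' populations, the per-site expected between-population difference is
#' `p1 * (1 - p2) + p2 * (1 - p1)`. Symmetric in its arguments and bounded
#' in \[0, 1\].
#'
#' @param p1,p2 allele frequencies in \[0, 1\] (vectorized).
#' @return Per-site d_XY values.
#' @examples
#' dxy_site(0.2, 0.7)  # 0.62
#' @export
dxy_site <- function(p1, p2) {
  if (any(!is.finite(p1)) || any(!is.finite(p2)) ||
      any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) {
    stop("allele frequencies must be in [0, 1]")
  }
  p1 * (1 - p2) + p2 * (1 - p1)
}

#' Per-site Hudson F_ST components
#'
#' Sample-size-corrected Hudson estimator components for one biallelic site:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. Components are combined per window as a ratio of
#' averages by [window_fst()]. Sites with an allele sample size below 2 are
#' dropped with a warning (the correction is undefined).
#'
#' @param ac1,n1,ac2,n2 alternate-allele count and allele sample size per
#'   population (vectorized).
#' @return Data frame with columns `numerator` and `denominator`, one row
#'   per retained site; a `kept` attribute holds the retained indices.
#' @export
fst_site <- function(ac1, n1, ac2, n2) {
  if (any(ac1 < 0 | ac2 < 0 | ac1 > n1 | ac2 > n2)) {
    stop("allele count outside [0, n]")
  }
  keep <- n1 >= 2 & n2 >= 2
  if (!all(keep)) {
    warning(sum(!keep), " site(s) skipped: allele sample size < 2")
    ac1 <- ac1[keep]; n1 <- n1[keep]; ac2 <- ac2[keep]; n2 <- n2[keep]
  }
  p1 <- ac1 / n1
  p2 <- ac2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- data.frame(numerator = num, denominator = den)
  attr(out, "kept") <- which(keep)
  out
}

#' Windowed Hudson F_ST (ratio of averages)
#'
#' Sums per-site Hudson numerator and denominator over the SNPs of each
#' window and reports their ratio. Windows with zero denominator (no
#' informative SNP) get `NA`. Negative window values are retained by
#' default; they carry rank information used by the repeatability
#' correlations.
#'
#' @param sites site-count data frame from [read_site_counts()] (columns
#'   `chrom`, `pos`, `ac1`, `n1`, `ac2`, `n2`), sorted by position.
#' @param layout a [genome_layout()].
#' @param clamp if `TRUE`, clamp negative window estimates to 0.
#' @return [layout_windows()] table with columns `fst` and `n_snps`.
#' @export
window_fst <- function(sites, layout, clamp = FALSE) {
  win <- layout_windows(layout)
  comp <- fst_site(sites$ac1, sites$n1, sites$ac2, sites$n2)
  kept <- attr(comp, "kept")
  wid <- assign_window(layout, sites$chrom[kept], sites$pos[kept])
  num <- tapply_sum(comp$numerator, wid, win$window)
  den <- tapply_sum(comp$denominator, wid, win$window)
  fst <- ifelse(den > 0, num / den, NA_real_)
  if (clamp) fst <- pmax(fst, 0)
  win$fst <- fst
  win$n_snps <- tapply_sum(rep(1, length(wid)), wid, win$window)
  win
}

# Sum `x` by group `g` onto the full level set `levels` (0 where absent).
tapply_sum <- function(x, g, levels) {
  s <- vapply(split(x, factor(g, levels = levels)), sum, numeric(1))
  unname(s[levels])
}

#' Per-window callable-site counts from a depth table
#'
#' A site is callable when its total read depth is at least three times the
#' sample size (about three reads per individual) and at most three times
#' the dataset-wide mean depth (guards against collapsed repeats and copy
#' number variants). Both multipliers are configurable.
#'
#' @param depth data frame with columns `chrom`, `pos` (1-based), `depth`.
#' @param sample_size number of individuals sequenced.
#' @param layout a [genome_layout()].
#' @param min_mult,max_mult lower/upper multipliers (defaults 3 and 3).
#' @return [layout_windows()] table with column `n_callable`.
#' @export
callable_sites <- function(depth, sample_size, layout, min_mult = 3, max_mult = 3) {
  if (nrow(depth) == 0) stop("empty depth table")
  mean_depth <- mean(depth$depth)
  ok <- depth$depth >= min_mult * sample_size & depth$depth <= max_mult * mean_depth
  win <- layout_windows(layout)
  wid <- assign_window(layout, depth$chrom[ok], depth$pos[ok])
  win$n_callable <- tapply_sum(rep(1, sum(ok)), wid, win$window)
  win
}

#' Windowed absolute differentiation (d_XY)
#'
#' Sums per-SNP [dxy_site()] values over each window and normalizes by the
#' window's callable-site count (variant and invariant sites passing the
#' depth filters). Windows with `min_sites` callable sites or fewer are set
#' to `NA`: with few sites the estimate is dominated by sampling noise.
#'
#' @param sites site-count data frame (needs `chrom`, `pos`, `p1`, `p2` or
#'   counts to derive them).
#' @param callable table with columns `window` and `n_callable`, e.g. from
#'   [callable_sites()].
#' @param layout a [genome_layout()].
#' @param min_sites callable-site threshold (default 5000; windows must
#'   exceed it).
#' @return [layout_windows()] table with columns `dxy`, `n_callable`,
#'   `n_snps`.
#' @export
window_dxy <- function(sites, callable, layout, min_sites = 5000) {
  win <- layout_windows(layout)
  ncall <- callable$n_callable[match(win$window, callable$window)]
  ncall[is.na(ncall)] <- 0
  if (is.null(sites$p1)) sites$p1 <- sites$ac1 / sites$n1
  if (is.null(sites$p2)) sites$p2 <- sites$ac2 / sites$n2
  d <- dxy_site(sites$p1, sites$p2)
  wid <- assign_window(layout, sites$chrom, sites$pos)
  nsnp <- tapply_sum(rep(1, length(wid)), wid, win$window)
  bad <- nsnp > 0 & ncall == 0
  if (any(bad)) {
    stop("window ", win$window[which(bad)[1]],
         " has SNPs but zero callable sites: inconsistent inputs")
  }
  dsum <- tapply_sum(d, wid, win$window)
  win$dxy <- ifelse(ncall > min_sites, dsum / ncall, NA_real_)
  win$n_callable <- ncall
  win$n_snps <- nsnp
  win
}

#' Windowed mean linkage disequilibrium
#'
#' Averages SNP-pair r-squared values per 100 kb window. Each pair is
#' assigned to the window containing the midpoint of its two positions;
#' pairs farther apart than `max_kb` kilobases are excluded (mirrors
#' upstream LD windowing; a SNP-count cap and the MAF > 0.05 filter are
#' applied when the pair list is produced).
#'
#' @param r2 data frame with columns `chrom`, `pos1`, `pos2`, `r2`.
#' @param layout a [genome_layout()].
#' @param max_kb maximum pair separation in kb (default 100).
#' @return [layout_windows()] table with columns `mean_ld` and `n_pairs`.
#' @export
window_ld <- function(r2, layout, max_kb = 100) {
  keep <- abs(r2$pos2 - r2$pos1) <= max_kb * 1000
  r2 <- r2[keep, , drop = FALSE]
  win <- layout_windows(layout)
  if (nrow(r2) == 0) {
    win$mean_ld <- NA_real_
    win$n_pairs <- 0
    return(win)
  }
  mid <- floor((r2$pos1 + r2$pos2) / 2)
  wid <- assign_window(layout, r2$chrom, mid)
  n <- tapply_sum(rep(1, length(wid)), wid, win$window)
  s <- tapply_sum(r2$r2, wid, win$window)
  win$mean_ld <- ifelse(n > 0, s / n, NA_real_)
  win$n_pairs <- n
  win
}

#' Harmonize window tables across population pairs
#'
#' Returns the set of windows with a non-missing value of `stat` in every
#' table — downstream analyses are limited to windows with data from all
#' pairs. Harmonization is done per statistic: a pair whose table has no
#' non-missing values at all for `stat` (e.g. a pair without d_XY
#' estimates) is dropped from that statistic's analyses only, with a
#' message.
#'
#' @param tables named list of window tables (data frames with `window` and
#'   the `stat` column).
#' @param stat column name to harmonize on (`"fst"` or `"dxy"`).
#' @return Character vector of common window IDs, with attribute `pairs`
#'   naming the retained tables.
#' @export
harmonize_windows <- function(tables, stat = "fst") {
  stopifnot(is.list(tables), length(tables) >= 2)
  if (is.null(names(tables))) names(tables) <- paste0("pair", seq_along(tables))
  has_stat <- vapply(tables, function(t) stat %in% names(t) && any(!is.na(t[[stat]])),
                     logical(1))
  if (any(!has_stat)) {
    message("dropping pair(s) without ", stat, " estimates: ",
            paste(names(tables)[!has_stat], collapse = ", "))
    tables <- tables[has_stat]
  }
  if (length(tables) < 2) stop("fewer than 2 pairs with ", stat, " estimates")
  universes <- lapply(tables, function(t) t$window)
  if (length(Reduce(intersect, universes)) == 0 &&
      all(lengths(universes) > 0)) {
    stop("window sets are disjoint: tables do not share a layout")
  }
  sets <- lapply(tables, function(t) t$window[!is.na(t[[stat]])])
  common <- Reduce(intersect, sets)
  if (length(common) == 0) warning("no windows shared by all pairs for ", stat)
  attr(common, "pairs") <- names(tables)
  common
}
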