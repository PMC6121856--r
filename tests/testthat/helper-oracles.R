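# Independent oracles and small fixture builders used across test files.

# Exhaustive hypergeometric upper-tail P(X >= k) from binomial coefficients.
hyper_tail_enum <- function(N, a, b, k) {
  lo <- max(0, a + b - N)
  hi <- min(a, b)
  js <- lo:hi
  pmf <- choose(a, js) * choose(N - a, b - js) / choose(N, b)
  sum(pmf[js >= k])
}

# Brute-force windowed Hudson F_ST: per-site loop, no shared code with the
# package implementation.
fst_window_brute <- function(sites, layout) {
  ws <- window_size(layout)
  num <- den <- list()
  for (i in seq_len(nrow(sites))) {
    n1 <- sites$n1[i]; n2 <- sites$n2[i]
    if (n1 < 2 || n2 < 2) next
    p1 <- sites$ac1[i] / n1
    p2 <- sites$ac2[i] / n2
    w <- paste0(sites$chrom[i], ":", floor((sites$pos[i] - 1) / ws) * ws)
    num[[w]] <- c(num[[w]], (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1))
    den[[w]] <- c(den[[w]], p1 * (1 - p2) + p2 * (1 - p1))
  }
  sapply(names(num), function(w) sum(num[[w]]) / sum(den[[w]]))
}

# d_XY by direct enumeration over two explicit haplotype matrices
# (rows = haplotypes, columns = sites, entries 0/1), normalized by the
# callable count.
dxy_enum <- function(h1, h2, callable) {
  total <- 0
  for (i in seq_len(nrow(h1))) {
    for (j in seq_len(nrow(h2))) {
      total <- total + sum(h1[i, ] != h2[j, ])
    }
  }
  total / (nrow(h1) * nrow(h2)) / callable
}

# Tiny layout used throughout: two chromosomes, window size 10 bp so peak
# and boundary logic is easy to reason about.
toy_layout <- function(lens = c(chrA = 100, chrB = 45), ws = 10) {
  genome_layout(names(lens), unname(lens), window_size = ws)
}

# Window table on a layout with given statistic values (recycled).
toy_table <- function(layout, fst = NULL, dxy = NULL) {
  win <- layout_windows(layout)
  if (!is.null(fst)) win$fst <- rep_len(fst, nrow(win))
  if (!is.null(dxy)) win$dxy <- rep_len(dxy, nrow(win))
  win
}

# Outlier set built directly from member/universe window IDs.
toy_outliers <- function(members, universe, stat = "fst", tail = "upper") {
  structure(list(statistic = stat, tail = tail, q = 0.05, threshold = NA,
                 members = members, universe = universe),
            class = "outlier_set")
}
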