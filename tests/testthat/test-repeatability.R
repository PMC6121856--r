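test_that("cross-pair correlation matrix is symmetric and order-invariant", {
  lay <- genome_layout("chr1", 2e6)
  set.seed(5)
  a <- toy_table(lay); a$fst <- runif(20)
  b <- toy_table(lay); b$fst <- a$fst * 0.5 + runif(20) * 0.5
  m <- correlate_pairs(list(a = a, b = b), "fst")
  expect_equal(m["a", "b"], m["b", "a"])
  expect_equal(m["a", "a"], 1)
  b_shuffled <- b[sample(nrow(b)), ]
  m2 <- correlate_pairs(list(a = a, b = b_shuffled), "fst")
  expect_equal(m["a", "b"], m2["a", "b"])  # matched on window IDs, not row order
  expect_error(correlate_pairs(list(a = a[1:2, ], b = b[1:2, ]), "fst"),
               "fewer than 3")
})

test_that("independent landscapes correlate near zero; shared weight raises r", {
  set.seed(21)
  n <- 1e4
  lay <- genome_layout("chr1", n * 1e5)
  L <- rnorm(n)
  mk <- function(w) {
    t <- toy_table(lay)
    t$fst <- plogis(w * L + sqrt(1 - w^2) * rnorm(n))
    t
  }
  r_at <- sapply(c(0, 0.4, 0.8), function(w) {
    m <- correlate_pairs(list(a = mk(w), b = mk(w)), "fst")
    m["a", "b"]
  })
  expect_lt(abs(r_at[1]), 0.05)
  expect_true(all(diff(r_at) > 0))  # monotone in the shared weight
})

test_that("variance explained squares the strongest coefficient per triangle", {
  m <- published_pair_correlations()
  fst <- variance_explained(m, triangle = "lower")
  dxy <- variance_explained(m, triangle = "upper")
  expect_equal(fst$max_r, 0.18)
  expect_equal(fst$pct_variance, 3)
  expect_equal(dxy$max_r, 0.51)
  expect_equal(dxy$pct_variance, 26)
  zero <- matrix(0, 3, 3)
  expect_equal(variance_explained(zero)$pct_variance, 0)
})

test_that("outlier calling takes strict empirical tails of the pair's own distribution", {
  lay <- genome_layout("chr1", 1e7)
  tbl <- toy_table(lay)
  tbl$fst <- 1:100
  up <- call_outliers(tbl, "fst", "upper", q = 0.05)
  expect_setequal(up$members, tbl$window[96:100])
  lo <- call_outliers(tbl, "fst", "lower", q = 0.05)
  expect_setequal(lo$members, tbl$window[1:5])
  expect_length(up$universe, 100)
  tbl$fst <- rep(1, 100)
  expect_warning(flat <- call_outliers(tbl, "fst", "upper"), "degenerate")
  expect_length(flat$members, 0)
  expect_error(call_outliers(tbl[1:10, ], "fst", "upper"), "at least 20")
})

test_that("overlap test matches exhaustive hypergeometric enumeration", {
  # oracle equivalence on an exhaustive small grid
  for (N in c(5, 9, 14, 20)) {
    universe <- paste0("w", seq_len(N))
    for (a in c(1, N %/% 3, N - 1)) {
      for (b in c(1, N %/% 2)) {
        for (k in 0:min(a, b)) {
          if (k < max(0, a + b - N)) next
          A <- toy_outliers(universe[seq_len(a)], universe)
          B <- toy_outliers(c(universe[seq_len(k)],
                              universe[(a + 1):N][seq_len(b - k)]), universe)
          r <- overlap_test(A, B)
          expect_equal(r$k, k)
          expect_equal(r$expected, a * b / N)
          expect_equal(r$p, hyper_tail_enum(N, a, b, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("overlap z and p behave at the extremes", {
  universe <- paste0("w", 1:1000)
  A <- toy_outliers(universe[1:50], universe)
  B <- toy_outliers(universe[51:100], universe)  # k = 0
  r <- overlap_test(A, B)
  expect_lt(r$z, 0)
  expect_equal(r$p, 1)  # P(X >= 0) = 1
  full <- overlap_test(A, A)  # maximal overlap
  expect_equal(full$k, 50)
  expect_lt(full$p, 1e-50)
  expect_error(overlap_test(A, toy_outliers("x1", paste0("x", 1:10))),
               "different universes")
})

test_that("adjacent outlier windows merge into maximal peaks", {
  lay <- toy_layout(c(chrA = 100, chrB = 45), ws = 10)
  A <- toy_outliers(c("chrA:0", "chrA:10", "chrA:40"), layout_windows(lay)$window)
  pk <- merge_peaks(A, lay)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$length, c(2L, 1L))
  expect_equal(pk$start, c(0, 40))
  expect_equal(pk$end, c(20, 50))
  # adjacency never crosses a chromosome boundary
  B <- toy_outliers(c("chrA:90", "chrB:0"), layout_windows(lay)$window)
  expect_equal(nrow(merge_peaks(B, lay)), 2)
  none <- toy_outliers(character(0), layout_windows(lay)$window)
  expect_equal(nrow(merge_peaks(none, lay)), 0)
})

test_that("peak permutation test: identity, disjoint chromosomes, bad input", {
  lay <- genome_layout(c("c1", "c2"), c(5e6, 5e6), window_size = 1e5)
  win <- layout_windows(lay)
  set.seed(9)
  A <- toy_outliers(sample(win$window[win$chrom == "c1"], 5), win$window)
  B <- toy_outliers(sample(win$window[win$chrom == "c2"], 5), win$window)
  pkA <- merge_peaks(A, lay); pkB <- merge_peaks(B, lay)
  res <- peak_overlap_permutation(pkA, pkB, lay, n_perm = 99, seed = 1)
  expect_equal(res$observed, 0)          # peaks confined to different chromosomes
  expect_gt(res$p, 0.5)
  same <- peak_overlap_permutation(pkA, pkA, lay, n_perm = 199, seed = 2)
  expect_equal(same$observed, nrow(pkA)) # identical peak sets: all shared
  expect_equal(same$p, 1 / 200)          # never matched by random placement
  expect_error(peak_overlap_permutation(pkA, pkB, lay, n_perm = 0), "n_perm")
  # peaks longer than the chromosome cannot be placed
  big <- data.frame(chrom = "c1", first = 0, last = 60, length = 61)
  tiny <- data.frame(chrom = "c1", first = 0, last = 0, length = 1)
  expect_error(peak_overlap_permutation(big, tiny, genome_layout("c1", 50e5, 1e5),
                                        n_perm = 9), "cannot be placed")
})

test_that("repeatability counts windows per pair and stays bounded", {
  universe <- paste0("w", 1:10)
  sets <- list(
    toy_outliers(c("w1", "w2"), universe),
    toy_outliers(c("w2", "w3"), universe),
    toy_outliers(c("w2"), universe)
  )
  rc <- repeatability_count(sets)
  expect_equal(rc$count[match(c("w1", "w2", "w3", "w4"), rc$window)],
               c(1L, 3L, 1L, 0L))
  expect_true(all(rc$count <= attr(rc, "n_pairs")))
  expect_error(repeatability_count(list(sets[[1]], toy_outliers("x", "x"))),
               "different universes")
})

test_that("p-value adjustment follows the Holm sequence", {
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  # hand-computed Holm: sorted p * (n - i + 1), cumulative max
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), method = "bh"),
               p.adjust(c(0.01, 0.02, 0.03), "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("overlap_table runs all pairwise tests with adjusted p-values", {
  universe <- paste0("w", 1:200)
  set.seed(2)
  sets <- lapply(1:4, function(i) toy_outliers(sample(universe, 10), universe))
  names(sets) <- paste0("s", 1:4)
  tab <- overlap_table(sets)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$p_adjusted >= tab$p))
})
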