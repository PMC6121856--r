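test_that("per-site d_XY follows the allele-frequency formula and is symmetric", {
  expect_equal(dxy_site(0.5, 0.5), 0.5)
  expect_equal(dxy_site(1, 0), 1)
  expect_equal(dxy_site(0.2, 0.7), 0.62)
  expect_error(dxy_site(1.2, 0.5), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(50); q <- runif(50)
  expect_equal(dxy_site(p, q), dxy_site(q, p))
  expect_true(all(dxy_site(p, q) >= 0 & dxy_site(p, q) <= 1))
})

test_that("Hudson per-site components match hand-evaluated formula", {
  comp <- fst_site(10, 20, 10, 20)
  expect_equal(comp$numerator, -0.5 / 19)   # equal p=0.5: correction dominates
  expect_equal(comp$denominator, 0.5)
  fixed <- fst_site(20, 20, 0, 20)
  expect_equal(fixed$numerator, 1)
  expect_equal(fixed$denominator, 1)
  mono <- fst_site(0, 20, 0, 20)
  expect_lte(mono$numerator, 0)
  expect_equal(mono$denominator, 0)
  expect_warning(skipped <- fst_site(c(1, 1), c(1, 20), c(0, 0), c(20, 20)),
                 "sample size < 2")
  expect_equal(nrow(skipped), 1)
  expect_error(fst_site(5, 4, 0, 10), "outside")
})

test_that("windowed Hudson F_ST equals brute-force per-site evaluation", {
  lay <- toy_layout(c(chrA = 200, chrB = 100), ws = 50)
  set.seed(42)
  n <- 80
  sites <- data.frame(
    chrom = sort(sample(c("chrA", "chrB"), n, replace = TRUE)),
    ac1 = rbinom(n, 20, 0.3), n1 = 20,
    ac2 = rbinom(n, 30, 0.6), n2 = 30
  )
  sites$pos <- unlist(lapply(split(seq_len(n), sites$chrom), function(i) {
    sort(sample.int(if (sites$chrom[i[1]] == "chrA") 200 else 100, length(i)))
  }), use.names = FALSE)
  wt <- window_fst(sites, lay)
  oracle <- fst_window_brute(sites, lay)
  got <- setNames(wt$fst, wt$window)[names(oracle)]
  expect_equal(unname(got), unname(oracle))
  # fixed differences everywhere -> exactly 1
  fixed <- data.frame(chrom = "chrA", pos = 1:10, ac1 = 20, n1 = 20, ac2 = 0, n2 = 20)
  expect_equal(window_fst(fixed, lay)$fst[1], 1)
  # negative estimates retained unless clamped
  same <- data.frame(chrom = "chrA", pos = 1:10, ac1 = 10, n1 = 20, ac2 = 10, n2 = 20)
  expect_lt(window_fst(same, lay)$fst[1], 0)
  expect_equal(window_fst(same, lay, clamp = TRUE)$fst[1], 0)
})

test_that("callable filter keeps 3*sample_size <= depth <= 3*mean_depth", {
  lay <- genome_layout("chr1", 1000)
  # mean depth 30: 29 fails the lower bound, 31 passes both
  d <- data.frame(chrom = "chr1", pos = 1:2, depth = c(29, 31))
  expect_equal(callable_sites(d, sample_size = 10, lay)$n_callable, 1)
  # mean depth 30: 91 exceeds 3*mean, 90 is allowed; rest fail the lower bound
  d2 <- data.frame(chrom = "chr1", pos = 1:4, depth = c(91, 9, 20, 0))
  expect_equal(callable_sites(d2, sample_size = 10, lay)$n_callable, 0)
  d3 <- data.frame(chrom = "chr1", pos = 1:4, depth = c(90, 90, 30, 30))
  expect_equal(callable_sites(d3, sample_size = 10, lay)$n_callable, 4)
  # uniform depth, fully covered window
  d4 <- data.frame(chrom = "chr1", pos = 1:1000, depth = 40)
  expect_equal(callable_sites(d4, sample_size = 10, lay)$n_callable, 1000)
  expect_error(callable_sites(d4[0, ], 10, lay), "empty")
})

test_that("windowed d_XY normalizes by callable sites and applies the site filter", {
  lay <- genome_layout("chr1", 3e5)
  callable <- data.frame(window = c("chr1:0", "chr1:100000", "chr1:200000"),
                         n_callable = c(10000, 4000, 10000))
  sites <- data.frame(chrom = "chr1", pos = c(10, 20),
                      ac1 = c(20, 20), n1 = 20, ac2 = c(0, 0), n2 = 20)
  wt <- window_dxy(sites, callable, lay)
  expect_equal(wt$dxy[1], 2e-4)          # two fixed differences over 10^4 sites
  expect_true(is.na(wt$dxy[2]))          # 4000 callable: below the >5000 filter
  expect_equal(wt$dxy[3], 0)             # no SNPs, enough callable sites
  # SNP in a window with no callable coverage is inconsistent
  bad <- data.frame(chrom = "chr1", pos = 150000, ac1 = 1, n1 = 20, ac2 = 0, n2 = 20)
  cal0 <- data.frame(window = "chr1:100000", n_callable = 0)
  expect_error(window_dxy(bad, cal0, lay), "zero callable")
})

test_that("windowed d_XY equals direct haplotype enumeration (oracle)", {
  set.seed(11)
  for (rep in 1:5) {
    L <- 100
    h1 <- matrix(rbinom(8 * L, 1, runif(1, 0.1, 0.5)), nrow = 8)
    h2 <- matrix(rbinom(6 * L, 1, runif(1, 0.2, 0.7)), nrow = 6)
    lay <- genome_layout("c", L, window_size = L)
    sites <- data.frame(chrom = "c", pos = 1:L,
                        ac1 = colSums(h1), n1 = 8, ac2 = colSums(h2), n2 = 6)
    callable <- data.frame(window = "c:0", n_callable = L)
    got <- window_dxy(sites, callable, lay, min_sites = 0)$dxy
    expect_equal(got, dxy_enum(h1, h2, L))
  }
})

test_that("window d_XY is invariant to splitting and recombining the SNP list", {
  lay <- genome_layout("chr1", 2e5)
  set.seed(3)
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(2e5, 300)),
                      ac1 = rbinom(300, 20, 0.4), n1 = 20,
                      ac2 = rbinom(300, 20, 0.6), n2 = 20)
  callable <- data.frame(window = c("chr1:0", "chr1:100000"), n_callable = 6000)
  full <- window_dxy(sites, callable, lay)
  half <- sample(nrow(sites), 150)
  a <- window_dxy(sites[half, ][order(sites$pos[half]), ], callable, lay)
  b <- window_dxy(sites[-half, ][order(sites$pos[-half]), ], callable, lay)
  expect_equal(full$dxy, a$dxy + b$dxy)
})

test_that("LD pairs are binned by midpoint with the distance cap", {
  lay <- genome_layout("chr1", 3e5)
  r2 <- data.frame(chrom = "chr1",
                   pos1 = c(10000, 90001, 95001, 10000),
                   pos2 = c(30000, 110001, 105001, 131000),
                   r2 = c(0.1, 0.3, 0.5, 0.9))
  wt <- window_ld(r2, lay)
  expect_equal(wt$mean_ld[1], 0.1)   # midpoint 20,000 -> first window
  expect_equal(wt$mean_ld[2], 0.4)   # midpoints 100,001 -> second window
  expect_equal(wt$n_pairs[1], 1)     # the 121 kb pair is excluded
  expect_equal(wt$n_pairs[2], 2)
})

test_that("harmonization intersects non-missing windows per statistic", {
  lay <- genome_layout("chr1", 4e5)
  a <- toy_table(lay, fst = 1)
  b <- toy_table(lay, fst = 1)
  a$fst[4] <- NA
  b$fst[1] <- NA
  common <- harmonize_windows(list(a = a, b = b), "fst")
  expect_setequal(common, c("chr1:100000", "chr1:200000"))

  b2 <- b; b2$fst <- NA
  expect_message(expect_error(harmonize_windows(list(a = a, b = b2), "fst"),
                              "fewer than 2"), "dropping")
  # a pair with no dxy drops from dxy analyses only
  a$dxy <- 0.01; b$dxy <- NA_real_
  c3 <- toy_table(lay, fst = 1); c3$dxy <- 0.02
  expect_message(common_dxy <- harmonize_windows(list(a = a, b = b, c = c3), "dxy"),
                 "dropping pair")
  expect_equal(attr(common_dxy, "pairs"), c("a", "c"))
  expect_length(common_dxy, 4)

  other <- toy_table(genome_layout("chr9", 4e5), fst = 1)
  expect_error(harmonize_windows(list(a = a, o = other), "fst"), "disjoint")
})
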