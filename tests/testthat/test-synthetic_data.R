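# Small layout shared by the generator tests (about 310 windows).
small_cfg <- function(...) {
  sim_config(macro = c(60, 50) * 1e6, intermediate = 30e6,
             micro = c(10, 6) * 1e6, ...)
}

test_that("generator is deterministic under a fixed seed", {
  a <- simulate_study(small_cfg(seed = 42))
  b <- simulate_study(small_cfg(seed = 42))
  expect_identical(a$features, b$features)
  expect_identical(a$tables, b$tables)
  expect_identical(a$meta, b$meta)
  c2 <- simulate_study(small_cfg(seed = 43))
  expect_false(identical(a$tables, c2$tables))
  s1 <- simulate_site_counts(rep(0.1, 4), genome_layout("c", 4e5), seed = 7,
                             emit_depth = FALSE)
  s2 <- simulate_site_counts(rep(0.1, 4), genome_layout("c", 4e5), seed = 7,
                             emit_depth = FALSE)
  expect_identical(s1$sites, s2$sites)
})

test_that("feature fields have the planted spatial structure", {
  st <- simulate_layout_features(small_cfg(seed = 5))
  f <- st$features
  # microchromosomes are more GC-rich on average
  expect_gt(mean(f$gc[f$size_class == "micro"]),
            mean(f$gc[f$size_class == "macro"]))
  # synonymous rate tracks GC
  expect_gt(cor(f$ds, f$gc), 0.3)
  # smooth fields: positive lag-1 autocorrelation, lost when scale is 0
  chr1 <- f$gc[f$chrom == "chr1"]
  ac1 <- cor(chr1[-1], chr1[-length(chr1)])
  white <- simulate_layout_features(small_cfg(seed = 5, feature_scale = 0))
  wchr1 <- white$features$gc[white$features$chrom == "chr1"]
  ac0 <- cor(wchr1[-1], wchr1[-length(wchr1)])
  expect_gt(ac1, 0.7)
  expect_lt(abs(ac0), 0.15)
  # one centromeric interval per macrochromosome, none on micros
  expect_equal(nrow(st$centromeres), 2)
  expect_true(all(f$centromere[f$size_class == "micro"] == 0))
})

test_that("shared weight controls cross-pair F_ST landscape correlation", {
  mean_r <- function(w, seed) {
    st <- simulate_study(small_cfg(seed = seed, shared_weight = w, stages = rep(1, 8)))
    mean(lower_triangle(correlate_pairs(st$tables, "fst")))
  }
  r0 <- mean(sapply(1:5, function(s) mean_r(0, s)))
  expect_lt(abs(r0), 0.02)
  # w = 1 with equal stages: noise term vanishes, correlation approaches 1
  expect_gt(mean_r(1, 1), 0.98)
  r_sweep <- sapply(c(0.3, 0.6, 0.9), mean_r, seed = 3)
  expect_true(all(diff(r_sweep) > 0))
})

test_that("F_ST repeatability rises with stage while d_XY stays flat", {
  st <- simulate_study(small_cfg(seed = 11, shared_weight = 0.8))
  fst_r <- correlate_pairs(st$tables, "fst")
  dxy_r <- correlate_pairs(st$tables, "dxy")
  s <- st$truth$stages
  prod_stage <- outer(s, s)[lower.tri(outer(s, s))]
  expect_gt(cor(lower_triangle(fst_r), prod_stage, method = "spearman"), 0.5)
  expect_lt(abs(cor(lower_triangle(dxy_r), prod_stage, method = "spearman")), 0.45)
  # d_XY still repeatable in itself (shared depression at constrained windows)
  expect_gt(mean(lower_triangle(dxy_r)), 0.1)
  # low-d_XY outliers co-locate with the high-latent windows
  low <- call_outliers(st$tables[[1]], "dxy", "lower")
  expect_gt(mean(st$truth$latent[low$members]), mean(st$truth$latent))
})

test_that("Balding-Nichols site counts reproduce target F_ST and respect limits", {
  lay <- genome_layout("c", 20 * 1e5)  # 20 windows
  # F near 0: windowed estimates center on 0
  s0 <- simulate_site_counts(rep(0, 20), lay, seed = 2, emit_depth = FALSE)
  expect_lt(abs(mean(window_fst(s0$sites, lay)$fst)), 0.01)
  sF <- simulate_site_counts(rep(0.1, 20), lay, seed = 3, emit_depth = FALSE)
  expect_lt(abs(mean(window_fst(sF$sites, lay)$fst) - 0.1), 0.03)
  expect_error(simulate_site_counts(rep(1, 20), lay), "\\[0, 1\\)")
  # emitted depth passes the callable filter everywhere
  lay2 <- genome_layout("c", 2e3, window_size = 1e3)
  sd1 <- simulate_site_counts(rep(0.1, 2), lay2, seed = 1, depth_stride = 1)
  cal <- callable_sites(sd1$depth, sd1$sample_size, lay2)
  expect_equal(sum(cal$n_callable), 2e3)
  # positions strictly increasing (valid site table)
  expect_silent(validated <- repscan:::validate_site_counts(sd1$sites))
})

test_that("continuum metadata maps stages to hybrid-zone ranges", {
  cfg <- small_cfg(seed = 6, stages = c(1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.25, 0.2))
  cm <- simulate_continuum_metadata(cfg)
  expect_equal(cm$meta$width_km[1], 0)        # completed speciation: no hybrid zone
  expect_equal(cm$meta$width_km[8], 600 * 0.8)
  expect_true(all(diff(cm$meta$width_km) > 0))   # stages sorted decreasing
  expect_true(all(diff(cm$meta$pct_hybrids) > 0))
  expect_gt(cor(cm$meta$cytb_pdist, cm$meta$stage), 0.8)
  expect_equal(dim(cm$control), c(8, 8))
  expect_true(isSymmetric(unclass(cm$control)))
})

test_that("invalid generator parameters are rejected and no_dxy is honoured", {
  expect_error(sim_config(shared_weight = 1.2), "shared_weight")
  expect_error(sim_config(stages = c(rep(0.5, 7), 0)), "stages")
  st <- simulate_study(small_cfg(seed = 9, no_dxy_pair = "pair_03"))
  expect_true(all(is.na(st$tables$pair_03$dxy)))
  expect_false(anyNA(st$tables$pair_03$fst))
  expect_message(common <- harmonize_windows(st$tables, "dxy"), "pair_03")
  expect_equal(length(attr(common, "pairs")), 7)
})
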