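#!/usr/bin/env Rscript
# Stage 3: repeatability of differentiation across the eight pairs.
#
# Three views of repeatability on the harmonized window set: (i) cross-pair
# correlation matrices of windowed F_ST and d_XY with the
# variance-explained worked summary; (ii) hypergeometric overlap of
# outlier windows (top 5% F_ST, bottom 5% d_XY) with z scores and
# Holm-adjusted one-sided p-values; (iii) peaks of adjacent outlier
# windows and a location-permutation test for one illustrative comparison;
# plus the per-window repeatability counts consumed by stage 05.

library(repscan)

sim <- "results/sim"
out <- "results/repeatability"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

layout <- read_layout(file.path(sim, "layout.tsv"))
pairs <- sort(sub("\\.bed$", "", basename(Sys.glob(file.path(sim, "pair_*.bed")))))
tables <- setNames(lapply(pairs, function(p) {
  read_window_table(file.path(sim, paste0(p, ".bed")))
}), pairs)

for (stat in c("fst", "dxy")) {
  tail <- if (stat == "fst") "upper" else "lower"
  m <- correlate_pairs(tables, stat)
  write_pair_matrix(m, file.path(out, paste0(stat, "_correlation.tsv")))
  ve <- variance_explained(m)
  cat(sprintf("%s: mean cross-pair r = %.3f over %d common windows; max r = %.2f (up to %d%% of variation explained)\n",
              toupper(stat), mean(lower_triangle(m)), attr(m, "n_windows"),
              ve$max_r, ve$pct_variance))

  common <- harmonize_windows(tables, stat)
  sets <- lapply(tables[attr(common, "pairs")], call_outliers, stat = stat,
                 tail = tail, universe = common)
  ov <- overlap_table(sets, adjust = "holm")
  write.table(ov, file.path(out, paste0(stat, "_overlap.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s outlier overlap: mean z = %.2f; %d / %d comparisons significant after Holm\n",
              toupper(stat), mean(ov$z), sum(ov$p_adjusted < 0.05), nrow(ov)))

  rc <- repeatability_count(sets)
  win <- layout_windows(layout)
  rc <- cbind(win[match(rc$window, win$window), c("chrom", "start", "end")], rc)
  write_window_table(rc, file.path(out, paste0(stat, "_repeatability.bed")),
                     layout = layout)
}

# peak-based overlap for the two most advanced pairs
sets_fst <- lapply(tables, call_outliers, stat = "fst", tail = "upper",
                   universe = harmonize_windows(tables, "fst"))
pkA <- merge_peaks(sets_fst[[7]], layout)
pkB <- merge_peaks(sets_fst[[8]], layout)
pt <- peak_overlap_permutation(pkA, pkB, layout, n_perm = 1000, seed = 42)
cat(sprintf("Peaks (%s vs %s): %d and %d peaks, %d shared; permutation p = %.4f (1000 location permutations)\n",
            pairs[7], pairs[8], nrow(pkA), nrow(pkB), pt$observed, pt$p))
cat("Repeatability outputs written under", out, "\n")
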