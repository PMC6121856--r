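---
title: "Repeatability of differentiation landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeatability of differentiation landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repscan)
```

## The question

Genome scans of closely related population pairs produce heterogeneous
landscapes: windows of elevated relative differentiation (F~ST~) and
depressed absolute divergence (d~XY~) recur along the genome. Two families
of processes can build them — selection protecting barrier loci against
gene flow, and linked selection (hitchhiking and background selection)
accelerating lineage sorting wherever gene density is high and
recombination low. The two are hard to tell apart within a single pair, but
they make different predictions *across* pairs: linked selection acts at
genomic features (gene density, recombination rate, centromeres,
chromosome structure) that are strongly conserved across birds, so it
should imprint the *same* landscape on independent divergence episodes.
`repscan` quantifies that repeatability in three ways (correlation
matrices, outlier-window overlap, shared peaks), asks whether it grows
along the speciation continuum, and attributes it to measurable genomic
features.

## Windowed estimators

**Coordinates.** Input site positions are 1-based (VCF convention);
windows are 0-based half-open `[start, start + 100000)` intervals (BED
convention), the last window of a chromosome possibly short. Window
identity is `"chrom:start"` and every analysis joins on it.

**F~ST~.** Per site we use Hudson's estimator with sample-size correction,

$$\hat N = (\hat p_1-\hat p_2)^2 - \frac{\hat p_1(1-\hat p_1)}{n_1-1}
 - \frac{\hat p_2(1-\hat p_2)}{n_2-1}, \qquad
 \hat D = \hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1),$$

and combine per window as a ratio of averages
$\sum \hat N / \sum \hat D$. Both choices matter: the corrected Hudson
estimator is unbiased in numerator and denominator separately
($E[\hat N] = (p_1-p_2)^2$, $E[\hat D]$ the expected heterozygosity
between populations), works directly on allele counts from either
individual or pooled sequencing, and the ratio-of-averages combination is
the standard way to stabilize window estimates (an average of per-site
ratios is dominated by low-information SNPs). Under the Balding–Nichols
model the population expectation of the ratio equals the model's F
exactly, which the test suite exploits. Sites with an allele sample size
below 2 are dropped (the correction is undefined); windows with zero
denominator are missing. Negative window estimates are *retained* by
default — they carry the rank information the repeatability correlations
use — with clamping to 0 available.

**d~XY~.** Per SNP, $d_{XY} = p_1(1-p_2) + p_2(1-p_1)$; per window, the
sum over SNPs divided by the number of *callable* sites (variant and
invariant), where callable means depth between 3× the sample size (about
three reads per individual) and 3× the dataset mean depth (guards against
collapsed repeats). Windows with 5000 callable sites or fewer are
missing: with few sites the normalization is dominated by noise. On
explicit haplotype data this estimator equals the mean pairwise
between-population difference per callable site, and the tests verify
that identity by direct enumeration.

**LD.** Mean r² of SNP pairs per window, each pair assigned to the window
containing the midpoint of its positions, pairs more than 100 kb apart
excluded. The MAF > 0.05 filter belongs to LD input preparation only —
F~ST~ and d~XY~ use all biallelic sites.

**Harmonization.** All cross-pair analyses run on the intersection of
windows non-missing in every pair, separately per statistic. A pair with
no d~XY~ at all (e.g. reduced-representation data failing the
callable-site filter) is dropped from d~XY~ analyses only.

## Repeatability statistics

**Correlations.** Pearson by default, so that squaring the strongest
coefficient reads directly as "up to X% of variance explained"; Spearman
is available. `variance_explained()` reports `round(100 * max(r)^2)` per
triangle, which reproduces the 3% / 26% worked example from the published
eight-pair matrix shipped in `extdata`.

**Outlier overlap.** Outliers are windows strictly beyond the empirical
5% quantile of the pair's own distribution (upper tail for F~ST~, lower
for d~XY~) within the harmonized universe. For two sets of sizes $a, b$
in a universe of $N$ windows, the overlap $k$ is hypergeometric under the
equal-probability null: $E = ab/N$,
$\mathrm{Var} = ab(N-a)(N-b)/(N^2(N-1))$, $z = (k-E)/\sqrt{\mathrm{Var}}$
(an effect size comparable across studies), one-sided $P(X \ge k)$, Holm
adjustment across comparisons (Benjamini–Hochberg available).

**Peaks.** Because adjacent outlier windows are not independent, maximal
runs of adjacent outliers are merged into peaks and the overlap statistic
becomes the number of peaks of one set intersecting any peak of the other
(both directions reported). Significance comes from 1000 location
permutations holding peak number and length fixed. Placement is uniform
over non-overlapping, *non-adjacent* arrangements on the original
chromosome: peaks are maximal runs, so valid configurations never contain
adjacent peaks, and this distribution is exactly the conditional law of
run locations for a uniform random outlier set given its run lengths —
with it the permutation p-values are exactly calibrated against
outlier-derived peaks, which the test suite checks. The p-value uses the
add-one estimator $(1 + \#\{perm \ge obs\})/(n_{perm}+1)$, which never
returns zero.

**Discreteness and calibration.** Both the hypergeometric tail and the
permutation p are discrete, hence super-uniform under the null; a
Kolmogorov–Smirnov test against U(0,1) would reject them for discreteness
alone. Both functions therefore expose `p_method = "randomized"` — the
fuzzy p-value $P(X > k) + U \cdot P(X = k)$, exactly uniform under the
null — which is the correct scale for calibration studies; defaults
remain the exact forms. The calibration suites verify z standardization
(mean 0, sd 1), uniformity of randomized p-values, and super-uniformity
of the exact ones.

## Continuum tests

Pair-level proxies of reproductive isolation (hybrid zone width, percent
hybrids, cytochrome-b p-distance computed by `p_distance()` as the mean
cross-group proportion of differing sites, and autosomal tree distance)
are turned into matrices by `scalar_to_matrix()`. The default entry is
the pairwise *mean* $(v_i+v_j)/2$: the hypothesis concerns the joint
progression of the two pairs being correlated, so an entry should be
extreme when both pairs sit at the same end of the continuum; `absdiff`
is provided as the alternative since the construction is a genuine
choice, not a reconstruction. The repeatability matrix enters as a
similarity (correlation coefficients); expected signs are therefore
negative for width/percent hybrids and positive for genetic distances.

`mantel()` correlates lower triangles (Spearman by default — with eight
pairs a rank coefficient plus permutation inference is the robust choice)
and permutes one matrix's label order; `partial_mantel()` uses the
first-order partial correlation controlling the phylogenetic distance
matrix, permutes the focal matrix's labels, and builds a percentile
bootstrap CI by resampling labels with replacement (self-pairs dropped) —
the CI procedure is a package choice, flagged as such. The test direction
is explicit (`alternative`); dimension below 4 is refused. The
implementation is cross-checked against `vegan::mantel` and
`vegan::mantel.partial` statistics in the tests, and its null size is
verified by simulation. Partial Mantel tests are known to be liberal in
some regimes; with n = 8 they are used here, as in comparative practice,
as evidence rather than proof.

## Feature GLMs

Repeatability counts (0–8 per window) are modelled as Poisson with log
link on seven predictors: GC fraction (recombination proxy, via GC-biased
gene conversion), d~s~ (mutation-rate proxy, consumed as a precomputed
column), gene count, mean LD r², chromosome size class (micro < 20 Mb,
macro > 40 Mb; 20–40 Mb chromosomes are excluded from the contrast by
default since the binary classification is silent about them — inclusion
as a third level is available), standardized position (k-th window from
the nearer end divided by ⌈W/2⌉, rising to 1 at the chromosome center)
and centromere overlap. Centromeres enter as an interval-overlap
indicator by default; because the published encoding of "proximity" is
not stated, a continuous `1 - standardized distance` alternative is
provided. Continuous predictors are z-scored so estimates are comparable
across predictors; rescaling a raw predictor provably leaves its scaled
estimate and p-value unchanged (tested to 1e-8). Significance uses the
sequential analysis of deviance (the base-R `anova` table); marginal
single-term deletions are available, and for the last term the two
coincide. Model fit is the correlation between observed counts and
fitted means. Collinearity is flagged via the condition number;
non-integer or negative responses are refused; an all-zero response is
fitted but flagged degenerate. When one response (counts across all
pairs) is modelled against several per-species feature sets, the models
share their response and are not independent — the analysis driver prints
that caveat.

## The generator

The generator is phenomenological: the analysis consumes window
statistics, so landscapes are simulated at field level (with an optional
Balding–Nichols site layer underneath) rather than via a coalescent
simulator — this gives exact control of the planted structure and keeps
full-genome, multi-seed suites cheap. Defaults describe the study
conditions the package targets:

- **Genome**: 9 macrochromosomes (50–150 Mb), 2 intermediates (25, 35
  Mb), 10 microchromosomes (5–19 Mb); 1026 Mb, 10,260 windows of 100 kb —
  an avian-like autosomal karyotype.
- **Features**: AR(1) fields with an autocorrelation scale of 20 windows
  (2 Mb, the scale of broad variation in avian GC and gene density);
  GC base 0.41 with a +0.05 microchromosome offset (micros are
  GC-richer), ~2 genes per 100 kb (denser on micros), d~s~ positively
  coupled to GC, mean LD elevated near centromeres, one ~2 Mb centromeric
  interval per macrochromosome.
- **Landscapes**: a latent constraint field $L$ = scaled combination of
  gene count (+0.5), GC (−0.5), centromere (+0.7), position (+0.4),
  standardized. Pair $p$ with stage $s_p$ gets the logit-F~ST~ field
  $s_p\,w\,L + \sqrt{1-w^2}\,\varepsilon_p$ around a stage-dependent
  baseline (mean F~ST~ 0.05–0.30 across stages, the realistic range for
  sister pairs of birds), mapped through the logistic. The shared weight
  defaults to $w = 0.6$, giving cross-pair correlations in the 0.02–0.36
  range observed in comparative scans. d~XY~ is
  $b_p(1 - 0.5\,L^+) + 0.3\,b_p\,\varepsilon$ truncated at zero, with
  per-pair baselines 0.004–0.012 per site — *stage-independent by
  construction*, encoding the interpretation that absolute divergence
  reflects processes accumulated over many speciation events, so its
  low-d~XY~ outliers co-locate across pairs regardless of stage.
- **Stages** default to 0.2–1.0 evenly spaced over 8 pairs; continuum
  metadata maps them to hybrid zone width $600(1-s)$ km, percent hybrids
  $70(1-s)$, and genetic distances increasing in $s$; the phylogenetic
  control matrix is the patristic matrix of a random coalescent tree,
  independent of stage.
- **Site layer**: per window, ancestral frequencies ~ U(0.05, 0.95),
  population frequencies Beta with parameters $p(1-F)/F$, binomial
  sampling at 50 alleles per population, uniform depth inside the
  callable band.

Everything derives from one integer seed; reruns are bit-identical.

**What passing tests do and do not show.** The generator reproduces the
statistical *structure* the analysis assumes — shared landscape, stage
modulation, feature-driven constraint — but not several properties of
real data: no linkage between adjacent windows beyond the feature
autocorrelation, no shared phylogenetic history among pairs (the control
matrix is independent noise, so the partial Mantel power estimate is
against an easy control), no gene flow, no Z chromosome, no
reference-bias or mapping artefacts, and feature fields are stationary
within chromosome classes. Recovery on these landscapes validates the
estimators and inference machinery, not the biological interpretation of
any real dataset.

## Numerical choices and degenerate inputs

- Outlier quantiles use R's default empirical quantile (type 7); members
  are strictly beyond the threshold, so a constant landscape yields an
  empty set with a warning rather than an arbitrary 5%.
- `overlap_test` with zero hypergeometric variance (empty or full sets)
  returns `z = NA` and flags it; `N = 0` is an error.
- Mantel permutation p-values use the add-one estimator; bootstrap
  resamples that collapse (fewer than 3 usable entries, or zero variance)
  are dropped from the CI.
- A control matrix collinear with the tested matrix (|r| > 0.999) warns;
  a constant control reduces the partial statistic to the plain Mantel
  statistic; a control identical to the tested matrix returns 0 by
  convention.
- Window assignment refuses positions beyond the chromosome end or below
  1; site tables must be strictly increasing within chromosome.
- Peak placement refuses configurations that cannot fit
  (`sum(lengths) + k - 1 > windows`).

## Problem sizes in the validation suites

The deeper suites run the full method at the sizes they state: exhaustive
hypergeometric enumeration for all universes up to N = 20; null
calibration with N = 2000 windows and 1000 (overlap) / 200 (peak
permutation × 199 permutations) replicates; Balding–Nichols recovery at
F = 0.1 with 50 alleles per population over 100 windows × 200 SNPs;
landscape recovery over 20 seeds × 3 shared weights at the full 10,260
windows × 8 pairs; continuum power over 100 replicate studies; GLM
recovery over 20 seeds at n = 5000 windows plus 1000 null replicates.
The complete suite runs in about a minute on one core.

## Known limitations

- The Hudson estimator is the single F~ST~ definition used; SFS- or
  genotype-likelihood-based estimators on the same data will differ
  numerically (rank structure is usually close).
- d~XY~ from pooled allele frequencies inherits pool-size noise that the
  callable-site filter only partly controls.
- Peak "overlap" counts intersecting peaks of one set against the other;
  the symmetric count is reported, but other definitions (shared windows
  after merging) are possible and available upstream of the permutation.
- With eight pairs, Mantel-type tests have limited resolution and the
  bootstrap CI is wide; treat the continuum analysis as directional
  evidence.
- The generator's fields are Gaussian on transformed scales; heavy-tailed
  landscape noise (e.g. recent sweeps) is not emulated.
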