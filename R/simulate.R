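#' Configuration for the synthetic multi-pair landscape generator
#'
#' Collects every parameter of the generator in one validated list. The
#' defaults describe the study conditions the analysis targets: eight
#' sister pairs of birds on an avian-like genome (~1 Gb split over macro-,
#' intermediate and microchromosomes, 100 kb windows), a shared
#' constraint landscape driven by genomic features, pair-specific noise,
#' and a divergence-stage parameter per pair that modulates how strongly
#' that pair's F_ST landscape expresses the shared component while d_XY
#' stays stage-independent.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param n_pairs number of population pairs (default 8).
#' @param macro,intermediate,micro chromosome lengths in bp for each size
#'   class.
#' @param window_size window size in bp (default 100 kb).
#' @param shared_weight `w` in \[0, 1\]: weight of the shared latent field
#'   in each pair's (logit) F_ST landscape (default 0.6).
#' @param stages per-pair divergence stages in (0, 1\] (default evenly
#'   spaced on \[0.2, 1\]).
#' @param noise_sd standard deviation of the pair-specific noise field.
#' @param feature_scale autocorrelation scale of the feature fields, in
#'   windows (0 gives white noise).
#' @param feature_betas named weights of the scaled features in the latent
#'   constraint field (gene_count +, gc -, centromere +, position +).
#' @param gc_base,gc_sd,micro_gc_offset GC field: baseline fraction, field
#'   sd, and the mean offset of microchromosomes (micros are more GC-rich).
#' @param gene_lambda mean genes per window.
#' @param ds_base,ds_gc_slope,ds_sd synonymous-rate field: baseline, slope
#'   on (GC - mean GC), residual sd.
#' @param centromere_mb centromeric interval length per macrochromosome, Mb.
#' @param fst_base,fst_stage_gain,fst_amp F_ST landscape: baseline mean,
#'   increase of the mean with stage, and amplitude of the logit field.
#' @param dxy_base_range range of per-pair baseline d_XY (per site).
#' @param dxy_weight,dxy_noise_sd depression of d_XY at high-constraint
#'   windows (applied to the positive part of the latent field) and
#'   relative noise sd; both stage-independent.
#' @param width_max_km,pct_hybrids_max continuum metadata ranges: hybrid
#'   zone width `width_max * (1 - stage)` km and percent hybrids
#'   `pct_max * (1 - stage)`.
#' @param no_dxy_pair optional pair name or index whose d_XY is withheld
#'   (emulates a pair without callable-site coverage).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_pairs = 8,
                       macro = c(150, 130, 120, 110, 90, 80, 70, 60, 50) * 1e6,
                       intermediate = c(35, 25) * 1e6,
                       micro = c(19, 16, 14, 12, 10, 9, 8, 7, 6, 5) * 1e6,
                       window_size = 1e5,
                       shared_weight = 0.6,
                       stages = NULL,
                       noise_sd = 1,
                       feature_scale = 20,
                       feature_betas = c(gene_count = 0.5, gc = -0.5,
                                         centromere = 0.7, position_index = 0.4),
                       gc_base = 0.41, gc_sd = 0.03, micro_gc_offset = 0.05,
                       gene_lambda = 2,
                       ds_base = 0.05, ds_gc_slope = 0.3, ds_sd = 0.008,
                       centromere_mb = 2,
                       fst_base = 0.05, fst_stage_gain = 0.25, fst_amp = 0.8,
                       dxy_base_range = c(0.004, 0.012),
                       dxy_weight = 0.5, dxy_noise_sd = 0.3,
                       width_max_km = 600, pct_hybrids_max = 70,
                       no_dxy_pair = NULL) {
  if (is.null(stages)) stages <- seq(0.2, 1, length.out = n_pairs)
  if (shared_weight < 0 || shared_weight > 1) stop("shared_weight must be in [0, 1]")
  if (any(stages <= 0 | stages > 1)) stop("stages must be in (0, 1]")
  if (length(stages) != n_pairs) stop("need one stage per pair")
  cfg <- as.list(environment())
  cfg$pairs <- sprintf("pair_%02d", seq_len(n_pairs))
  class(cfg) <- "sim_config"
  cfg
}

# Stationary AR(1) field of length n with autocorrelation scale in steps.
smooth_field <- function(n, scale) {
  e <- stats::rnorm(n)
  if (scale <= 0 || n == 1) return(e)
  phi <- exp(-1 / scale)
  x <- numeric(n)
  x[1] <- e[1]
  for (t in 2:n) x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * e[t]
  x
}

#' Simulate a genome layout and per-window genomic features
#'
#' Builds an avian-like layout and smooth (spatially autocorrelated)
#' feature fields: GC fraction (higher on microchromosomes), gene counts,
#' a synonymous-rate field positively correlated with GC, a mean-LD field
#' elevated near centromeres, one centromeric interval per macrochromosome,
#' plus the deterministic position index and size class.
#'
#' @param config a [sim_config()].
#' @return List: `layout` ([genome_layout()]), `features` (window table),
#'   `centromeres` (interval table).
#' @export
simulate_layout_features <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lens <- c(config$macro, config$intermediate, config$micro)
  layout <- genome_layout(paste0("chr", seq_along(lens)), lens,
                          window_size = config$window_size)
  win <- position_index(layout)
  win$size_class <- size_class(layout$length[match(win$chrom, layout$chrom)])
  n_macro <- length(config$macro)
  cent <- data.frame(chrom = layout$chrom[seq_len(n_macro)],
                     start = NA_real_, end = NA_real_)
  for (i in seq_len(n_macro)) {
    len <- layout$length[i]
    clen <- min(config$centromere_mb * 1e6, len / 4)
    lo <- 0.2 * len
    cent$start[i] <- floor(stats::runif(1, lo, 0.8 * len - clen))
    cent$end[i] <- cent$start[i] + clen
  }
  cm <- centromere_flag(layout, cent)
  win$centromere <- cm$centromere[match(win$window, cm$window)]
  per_chrom_field <- function() {
    unlist(lapply(split(win$window, factor(win$chrom, levels = layout$chrom)),
                  function(w) smooth_field(length(w), config$feature_scale)),
           use.names = FALSE)
  }
  ord <- order(match(win$chrom, layout$chrom), win$start)
  stopifnot(identical(ord, seq_len(nrow(win))))  # layout_windows is ordered
  f_gc <- per_chrom_field()
  f_gene <- per_chrom_field()
  f_ld <- per_chrom_field()
  micro <- win$size_class == "micro"
  win$gc <- pmin(0.75, pmax(0.25,
    config$gc_base + config$micro_gc_offset * micro + config$gc_sd * f_gc))
  win$gene_count <- stats::rpois(nrow(win),
    exp(log(config$gene_lambda) + 0.4 * f_gene + 0.3 * micro))
  win$ds <- pmax(0.001, config$ds_base +
    config$ds_gc_slope * (win$gc - mean(win$gc)) + config$ds_sd * stats::rnorm(nrow(win)))
  win$mean_ld <- stats::plogis(stats::qlogis(0.2) + 0.5 * f_ld + 0.8 * win$centromere)
  list(layout = layout, features = win, centromeres = cent)
}

# Latent constraint field: planted linear combination of scaled features.
latent_field <- function(features, betas) {
  z <- function(x) (x - mean(x)) / stats::sd(x)
  L <- betas[["gene_count"]] * z(features$gene_count) +
       betas[["gc"]] * z(features$gc) +
       betas[["centromere"]] * features$centromere +
       betas[["position_index"]] * z(features$position_index)
  z(L)
}

#' Simulate per-pair F_ST and d_XY landscapes with planted shared structure
#'
#' A latent constraint field `L` (linked selection at gene-dense,
#' low-recombination, centromeric, chromosome-central windows) is combined
#' per pair with pair-specific noise. For pair `p` with stage `s_p` and
#' shared weight `w`, the logit-scale F_ST field is
#' `s_p * w * L + sqrt(1 - w^2) * eps_p`, shifted by a stage-dependent
#' baseline and mapped to (0, 1): later-stage pairs express the shared
#' component more strongly. d_XY is generated stage-independently as
#' `baseline_p * (1 - d_w * max(L, 0)) + noise`, truncated at 0, so
#' low-d_XY outliers co-locate across all pairs regardless of stage —
#' absolute divergence reflects processes accumulated over many
#' speciation events, not the current episode.
#'
#' @param layout,features from [simulate_layout_features()].
#' @param config a [sim_config()].
#' @return List: `tables` (named list of per-pair window tables with `fst`
#'   and `dxy`), `truth` (latent field, stages, planted coefficients,
#'   per-pair baselines).
#' @export
simulate_pair_landscapes <- function(layout, features, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  w <- config$shared_weight
  L <- latent_field(features, config$feature_betas)
  n <- nrow(features)
  dxy_base <- stats::runif(config$n_pairs, config$dxy_base_range[1],
                           config$dxy_base_range[2])
  tables <- list()
  for (p in seq_len(config$n_pairs)) {
    s <- config$stages[p]
    eps <- config$noise_sd * stats::rnorm(n)
    eta <- stats::qlogis(config$fst_base + config$fst_stage_gain * s) +
      config$fst_amp * (s * w * L + sqrt(1 - w^2) * eps)
    tab <- features[, c("chrom", "start", "end", "window")]
    tab$fst <- stats::plogis(eta)
    dxy <- dxy_base[p] * (1 - config$dxy_weight * pmax(L, 0)) +
      dxy_base[p] * config$dxy_noise_sd * stats::rnorm(n)
    tab$dxy <- pmax(dxy, 0)
    tables[[config$pairs[p]]] <- tab
  }
  if (!is.null(config$no_dxy_pair)) {
    nm <- if (is.numeric(config$no_dxy_pair)) config$pairs[config$no_dxy_pair]
          else config$no_dxy_pair
    tables[[nm]]$dxy <- NA_real_
  }
  truth <- list(latent = stats::setNames(L, features$window),
                stages = stats::setNames(config$stages, config$pairs),
                feature_betas = config$feature_betas,
                shared_weight = w, dxy_base = stats::setNames(dxy_base, config$pairs))
  list(tables = tables, truth = truth)
}

#' Simulate per-site allele counts under the Balding-Nichols model
#'
#' For each window with target differentiation `F`, SNP ancestral
#' frequencies are drawn uniformly on (0.05, 0.95) and the two population
#' frequencies from `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` (degenerate
#' at `p` when `F = 0`); allele counts are binomial at `n_alleles`
#' chromosomes per population. A uniform depth field passing the callable
#' filter is emitted alongside (optionally thinned with `depth_stride`).
#'
#' @param fst_targets numeric vector of per-window target F_ST in \[0, 1),
#'   aligned with `layout_windows(layout)`.
#' @param layout a [genome_layout()].
#' @param n_alleles allele sample size per population (default 50).
#' @param snps_per_window SNPs simulated per window (default 200).
#' @param seed integer seed.
#' @param emit_depth write the per-site depth table (default `TRUE`).
#' @param depth_stride emit depth every `depth_stride` bases (default 1).
#' @param depth_mean constant depth value (default `4 * n_alleles / 2`,
#'   comfortably inside the callable band for `n_alleles / 2` individuals).
#' @return List: `sites` (site-count table), `depth` (or `NULL`),
#'   `sample_size` (individuals, for [callable_sites()]).
#' @export
simulate_site_counts <- function(fst_targets, layout, n_alleles = 50,
                                 snps_per_window = 200, seed = 1,
                                 emit_depth = TRUE, depth_stride = 1,
                                 depth_mean = 2 * n_alleles) {
  set.seed(seed)
  win <- layout_windows(layout)
  stopifnot(length(fst_targets) == nrow(win))
  if (any(fst_targets >= 1 | fst_targets < 0)) stop("F targets must be in [0, 1)")
  S <- snps_per_window
  pieces <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    len <- win$end[i] - win$start[i]
    k <- min(S, len)
    pos <- win$start[i] + sort(sample.int(len, k))
    p <- stats::runif(k, 0.05, 0.95)
    F <- fst_targets[i]
    if (F < 1e-12) {
      p1 <- p; p2 <- p
    } else {
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      p1 <- stats::rbeta(k, a, b)
      p2 <- stats::rbeta(k, a, b)
    }
    pieces[[i]] <- data.frame(chrom = win$chrom[i], pos = pos,
                              ac1 = stats::rbinom(k, n_alleles, p1), n1 = n_alleles,
                              ac2 = stats::rbinom(k, n_alleles, p2), n2 = n_alleles,
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, pieces)
  sites$p1 <- sites$ac1 / sites$n1
  sites$p2 <- sites$ac2 / sites$n2
  depth <- NULL
  if (emit_depth) {
    dp <- lapply(seq_len(nrow(layout)), function(i) {
      pos <- seq(1, layout$length[i], by = depth_stride)
      data.frame(chrom = layout$chrom[i], pos = pos, depth = depth_mean,
                 stringsAsFactors = FALSE)
    })
    depth <- do.call(rbind, dp)
  }
  list(sites = sites, depth = depth, sample_size = n_alleles / 2)
}

#' Simulate continuum metadata and a phylogenetic control matrix
#'
#' Hybrid zone width and percent hybrids decrease linearly with divergence
#' stage (`width_max * (1 - s)` km, `pct_max * (1 - s)` %); cytochrome-b
#' p-distance and autosomal tree distance increase with stage. The control
#' matrix is the patristic distance matrix of a random coalescent tree
#' over the pairs (a stand-in for an inferred phylogeny, independent of
#' stage by construction).
#'
#' @param config a [sim_config()].
#' @return List: `meta` (data frame `pair`, `stage`, `width_km`,
#'   `pct_hybrids`, `cytb_pdist`, `auto_dist`), `control`
#'   ([pair_matrix()]).
#' @export
simulate_continuum_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  s <- config$stages
  meta <- data.frame(
    pair = config$pairs,
    stage = s,
    width_km = config$width_max_km * (1 - s),
    pct_hybrids = config$pct_hybrids_max * (1 - s),
    cytb_pdist = pmax(0, 0.002 + 0.08 * s + stats::rnorm(config$n_pairs, 0, 0.004)),
    auto_dist = pmax(0, 0.002 + 0.02 * s + stats::rnorm(config$n_pairs, 0, 0.001)),
    stringsAsFactors = FALSE
  )
  tree <- ape::rcoal(config$n_pairs, tip.label = config$pairs)
  control <- stats::cophenetic(tree)[config$pairs, config$pairs]
  list(meta = meta, control = pair_matrix(control))
}

#' Run the full generator
#'
#' Convenience wrapper chaining [simulate_layout_features()],
#' [simulate_pair_landscapes()] and [simulate_continuum_metadata()].
#'
#' @param config a [sim_config()].
#' @return List: `layout`, `features`, `centromeres`, `tables`, `truth`,
#'   `meta`, `control`.
#' @export
simulate_study <- function(config = sim_config()) {
  lf <- simulate_layout_features(config)
  pl <- simulate_pair_landscapes(lf$layout, lf$features, config)
  cm <- simulate_continuum_metadata(config)
  c(lf, pl, cm)
}
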