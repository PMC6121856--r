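#' Standardized window position along the chromosome
#'
#' For a chromosome of `W` windows, the k-th window from the nearer end
#' gets index `k / ceiling(W / 2)`: values rise from near 0 at the
#' chromosome ends to 1 at the center and are symmetric about it.
#'
#' @param layout a [genome_layout()].
#' @return [layout_windows()] table with column `position_index` in (0, 1].
#' @export
position_index <- function(layout) {
  win <- layout_windows(layout)
  pieces <- lapply(split(seq_len(nrow(win)), win$chrom), function(rows) {
    W <- length(rows)
    i <- seq_len(W)
    k <- pmin(i, W + 1 - i)
    k / ceiling(W / 2)
  })
  idx <- numeric(nrow(win))
  for (ch in names(pieces)) idx[win$chrom == ch] <- pieces[[ch]]
  win$position_index <- idx
  win
}

#' Chromosome size class
#'
#' Avian genomes mix micro- and macrochromosomes: micro below 20 Mb, macro
#' above 40 Mb; chromosomes in between are classed `intermediate` and by
#' default excluded from the binary size contrast.
#'
#' @param length chromosome length(s) in bp.
#' @param micro_max,macro_min class boundaries in bp.
#' @return Factor with levels `micro`, `intermediate`, `macro`.
#' @export
size_class <- function(length, micro_max = 20e6, macro_min = 40e6) {
  cls <- ifelse(length < micro_max, "micro",
                ifelse(length > macro_min, "macro", "intermediate"))
  factor(cls, levels = c("micro", "intermediate", "macro"))
}

#' Centromere overlap indicator or proximity
#'
#' `encoding = "indicator"` (default): 1 if the window overlaps any
#' centromeric interval on its chromosome, else 0. `encoding =
#' "proximity"`: `1 - d / d_max` where `d` is the distance from the window
#' midpoint to the nearest centromeric interval on the chromosome and
#' `d_max` the largest such distance on that chromosome (1 inside the
#' interval, falling to 0 at the farthest window); chromosomes without an
#' interval get 0 throughout.
#'
#' @param layout a [genome_layout()].
#' @param centromeres data frame `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_centromeres()].
#' @param encoding `"indicator"` or `"proximity"`.
#' @return [layout_windows()] table with column `centromere`.
#' @export
centromere_flag <- function(layout, centromeres, encoding = c("indicator", "proximity")) {
  encoding <- match.arg(encoding)
  win <- layout_windows(layout)
  win$centromere <- 0
  for (ch in unique(centromeres$chrom)) {
    ivs <- centromeres[centromeres$chrom == ch, , drop = FALSE]
    rows <- which(win$chrom == ch)
    if (!length(rows)) next
    if (encoding == "indicator") {
      hit <- rep(FALSE, length(rows))
      for (i in seq_len(nrow(ivs))) {
        hit <- hit | (win$start[rows] < ivs$end[i] & win$end[rows] > ivs$start[i])
      }
      win$centromere[rows] <- as.numeric(hit)
    } else {
      mid <- (win$start[rows] + win$end[rows]) / 2
      d <- rep(Inf, length(rows))
      for (i in seq_len(nrow(ivs))) {
        di <- pmax(0, pmax(ivs$start[i] - mid, mid - ivs$end[i]))
        d <- pmin(d, di)
      }
      dmax <- max(d)
      win$centromere[rows] <- if (dmax > 0) 1 - d / dmax else 1
    }
  }
  win
}

#' Poisson GLM of repeatability counts on genomic features
#'
#' Fits `count ~ features` with a Poisson distribution and log link on
#' complete-case windows. Continuous predictors are z-scored so estimates
#' are comparable across predictors; factors (size class, centromere
#' indicator) enter as-is. Per-predictor significance comes from an
#' analysis of deviance (`test = "sequential"` is the base-R `anova` table;
#' `"marginal"` uses single-term deletions). Model fit is summarized as the
#' correlation between observed counts and fitted means.
#'
#' @param counts data frame `window`, `count` from [repeatability_count()].
#' @param features data frame keyed by `window` with predictor columns.
#' @param predictors character vector of predictor column names (default:
#'   all feature columns except coordinates).
#' @param scale z-score continuous predictors (default `TRUE`).
#' @param test `"sequential"` or `"marginal"` deviance tests.
#' @param drop_intermediate drop windows on intermediate-size chromosomes
#'   when `size_class` is among the predictors (default `TRUE`).
#' @return Object of class `glm_fit`: list with `table` (term, estimate,
#'   se, p), `model_fit_r`, `n`, the fitted `model`, and `degenerate` flag.
#' @export
fit_repeatability_glm <- function(counts, features, predictors = NULL,
                                  scale = TRUE, test = c("sequential", "marginal"),
                                  drop_intermediate = TRUE) {
  test <- match.arg(test)
  df <- merge(counts[, c("window", "count")], features, by = "window")
  if (is.null(predictors)) {
    predictors <- setdiff(names(features), c("window", "chrom", "start", "end"))
  }
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("response must be non-negative integer counts")
  }
  if ("size_class" %in% predictors && drop_intermediate &&
      is.factor(df$size_class)) {
    df <- df[df$size_class != "intermediate", , drop = FALSE]
    df$size_class <- droplevels(df$size_class)
    if (nlevels(df$size_class) < 2) predictors <- setdiff(predictors, "size_class")
  }
  df <- df[stats::complete.cases(df[, c("count", predictors)]), , drop = FALSE]
  if (nrow(df) < 10 * length(predictors)) {
    stop("need at least 10 rows per predictor (", nrow(df), " complete rows)")
  }
  degenerate <- all(df$count == 0)
  if (degenerate) warning("all counts zero: intercept-only degenerate fit")
  for (v in predictors) {
    if (is.numeric(df[[v]]) && scale) {
      s <- stats::sd(df[[v]])
      if (s == 0) {
        warning("constant predictor dropped: ", v)
        predictors <- setdiff(predictors, v)
      } else {
        df[[v]] <- (df[[v]] - mean(df[[v]])) / s
      }
    }
  }
  X <- df[, predictors, drop = FALSE]
  num <- vapply(X, is.numeric, logical(1))
  if (sum(num) >= 2) {
    kappa_x <- kappa(stats::cor(X[, num, drop = FALSE]), exact = TRUE)
    if (kappa_x > 100) warning("collinear predictors: condition number ",
                               format(kappa_x, digits = 3))
  }
  form <- stats::as.formula(paste("count ~", paste(predictors, collapse = " + ")))
  fit <- stats::glm(form, family = stats::poisson(), data = df)
  cf <- summary(fit)$coefficients
  pvals <- if (test == "sequential") {
    an <- stats::anova(fit, test = "Chisq")
    stats::setNames(an[["Pr(>Chi)"]][-1], rownames(an)[-1])
  } else {
    d1 <- stats::drop1(fit, test = "Chisq")
    stats::setNames(d1[["Pr(>Chi)"]][-1], rownames(d1)[-1])
  }
  # coefficient rows mapped back to their model term (factors expand)
  assign_idx <- attr(stats::model.matrix(fit), "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  term_of <- c("(Intercept)", terms_lab)[assign_idx + 1]
  tab <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    p = pvals[term_of], row.names = NULL, stringsAsFactors = FALSE)
  obs <- df$count
  model_fit_r <- if (stats::sd(fitted(fit)) > 0 && stats::sd(obs) > 0) {
    stats::cor(obs, fitted(fit))
  } else NA_real_
  structure(list(table = tab, model_fit_r = model_fit_r, n = nrow(df),
                 model = fit, degenerate = degenerate, test = test),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Poisson GLM of repeatability on %d windows (%s deviance tests)\n",
              x$n, x$test))
  tab <- x$table
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$signif <- ifelse(is.na(tab$p), "", ifelse(tab$p < 0.001, "***",
                ifelse(tab$p < 0.01, "**", ifelse(tab$p < 0.05, "*", ""))))
  print(tab)
  cat(sprintf("model_fit_r (observed vs fitted): %.3f\n", x$model_fit_r))
  invisible(x)
}

#' GC fraction of windows from a sequence set (convenience helper)
#'
#' @param seqs named character vector or list of chromosome sequences
#'   (names matching the layout), or a FASTA path.
#' @param layout a [genome_layout()].
#' @return [layout_windows()] table with column `gc` (fraction of G/C among
#'   unambiguous bases; `NA` if a window has none).
#' @export
window_gc <- function(seqs, layout) {
  seqs <- load_alignment(seqs)
  win <- layout_windows(layout)
  win$gc <- NA_real_
  for (i in seq_len(nrow(win))) {
    s <- seqs[[win$chrom[i]]]
    if (is.null(s)) next
    piece <- s[(win$start[i] + 1):min(win$end[i], length(s))]
    acgt <- piece %in% c("a", "c", "g", "t")
    if (any(acgt)) win$gc[i] <- mean(piece[acgt] %in% c("g", "c"))
  }
  win
}
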