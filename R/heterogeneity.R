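# Intratumor diversity and immune-infiltrate statistics: four-population
# fractions, Shannon entropy, exact small-sample Wilcoxon tests, pooled
# chi-square comparison, diversity-CD8 regression, and topology maps.

#' Shannon entropy of a proportion vector
#'
#' `-sum(p_i * log(p_i))` over nonzero entries (the limit convention
#' `p log p -> 0` as `p -> 0`). Proportions are renormalized to sum to 1.
#'
#' @param p nonnegative proportions (or counts).
#' @param base logarithm base; natural log (nats) by default, use 2 for bits.
#' @return nonnegative entropy; at most `log(length(p), base)`.
#' @export
shannon_entropy <- function(p, base = exp(1)) {
  if (any(p < 0) || all(p == 0)) stop("`p` must be nonnegative, not all zero")
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Summarize a slide's cell populations
#'
#' @param cells CellRecord data.frame (needs a `population` column; `cd8`
#'   and `gzmb` logical columns are used when present).
#' @param montages optional per-cell field/montage identifier; CD8 counts
#'   are then averaged per montage ("average counts of at least three
#'   montages per sample" convention). When NULL the total CD8 count is
#'   reported.
#' @param slide_id,timepoint identifiers carried into the summary;
#'   `timepoint` is one of baseline, cycle2, primary, metastasis.
#' @param base entropy log base.
#' @return object of class `slide_summary`: slide_id, timepoint, n_cells,
#'   fractions (named 4-vector in [population_levels()] order), shannon,
#'   cd8_per_montage, gzmb_fraction.
#' @export
summarize_slide <- function(cells, montages = NULL, slide_id = NA,
                            timepoint = NA, base = exp(1)) {
  if (is.null(cells) || nrow(cells) == 0L) {
    return(structure(list(slide_id = slide_id, timepoint = timepoint,
                          n_cells = 0L, fractions = rep(NA_real_, 4L),
                          shannon = NA_real_, cd8_per_montage = NA_real_,
                          gzmb_fraction = NA_real_, undefined = TRUE),
                     class = "slide_summary"))
  }
  pop <- factor(cells$population, levels = population_levels())
  if (anyNA(pop)) stop("unknown population labels in `cells`")
  counts <- table(pop)
  frac <- as.numeric(counts) / nrow(cells)
  names(frac) <- population_levels()
  cd8 <- if ("cd8" %in% names(cells)) cells$cd8 else NULL
  cd8_per_montage <- NA_real_
  gzmb_fraction <- NA_real_
  if (!is.null(cd8) && !all(is.na(cd8))) {
    cd8 <- isTRUE_vec(cd8)
    if (!is.null(montages)) {
      stopifnot(length(montages) == nrow(cells))
      cd8_per_montage <- mean(tapply(cd8, montages, sum))
    } else {
      cd8_per_montage <- sum(cd8)
    }
    if ("gzmb" %in% names(cells) && sum(cd8) > 0) {
      gz <- isTRUE_vec(cells$gzmb)
      gzmb_fraction <- sum(gz & cd8) / sum(cd8)
    }
  }
  structure(list(slide_id = slide_id, timepoint = timepoint,
                 n_cells = nrow(cells), fractions = frac,
                 shannon = shannon_entropy(frac + 0, base = base),
                 cd8_per_montage = cd8_per_montage,
                 gzmb_fraction = gzmb_fraction, undefined = FALSE),
            class = "slide_summary")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.slide_summary <- function(x, ...) {
  cat(sprintf("Slide %s (%s): %d cells, Shannon %.4f nats\n",
              x$slide_id, x$timepoint, x$n_cells, x$shannon))
  print(round(x$fractions, 3))
  invisible(x)
}

comparison_result <- function(statistic, p_value, test_name, n) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 test_name = test_name, n = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

# distribution of the sum of `na` doubled midranks chosen without
# replacement from `dr` (all integers): matrix counts[k+1, s+1]
rank_sum_counts <- function(dr, na) {
  smax <- sum(dr)
  f <- matrix(0, nrow = na + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (d in dr) {
    kmax <- na
    for (k in kmax:1L) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) {
        f[k + 1L, nz + d] <- f[k + 1L, nz + d] + f[k, nz]
      }
    }
  }
  f[na + 1L, ]
}

#' Exact Wilcoxon rank-sum test (midranks, conditional enumeration)
#'
#' Two-sided Wilcoxon-Mann-Whitney test. For small samples
#' (`length(x) + length(y) <= exact_limit`) the p-value is computed from
#' the exact conditional distribution of the rank sum given the observed
#' (possibly tied) pooled values, by dynamic programming over midranks;
#' the two-sided p is `P(|W - E(W)| >= |w - E(W)|)`. Larger samples use
#' the tie-corrected normal approximation.
#'
#' @param x,y numeric samples.
#' @param exact_limit total-size cutoff for exact computation (default 40).
#' @return [comparison_result] with test_name `"wilcoxon_rank_sum"`;
#'   statistic is the rank sum of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 40L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  na <- length(x); nb <- length(y); n <- na + nb
  r <- rank(c(x, y))
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_limit) {
    dr <- as.integer(round(2 * r))
    cnt <- rank_sum_counts(dr, na)
    s <- seq_along(cnt) - 1L
    dev <- abs(s - 2 * mu)
    obs <- abs(2 * w - 2 * mu)
    p <- sum(cnt[dev >= obs - 1e-9]) / sum(cnt)
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  comparison_result(w, min(p, 1), "wilcoxon_rank_sum", c(na, nb))
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on `x - y`. Zero differences are dropped;
#' midranks of the absolute differences handle ties. For `m <=
#' exact_limit` nonzero pairs the null distribution is enumerated exactly
#' (dynamic programming over the 2^m sign assignments); otherwise the
#' tie-corrected normal approximation is used.
#'
#' @param x,y paired numeric samples of equal length.
#' @param exact_limit cutoff for exact computation (default 25).
#' @return [comparison_result] with test_name `"wilcoxon_signed_rank"`;
#'   statistic is the positive-rank sum V.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    return(comparison_result(0, 1, "wilcoxon_signed_rank", length(x)))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (m <= exact_limit) {
    dr <- as.integer(round(2 * r))
    # counts of subset sums over all 2^m subsets (subset = positive signs)
    g <- numeric(sum(dr) + 1L); g[1L] <- 1
    for (dd in dr) {
      nz <- which(g > 0)
      g2 <- g
      g2[nz + dd] <- g2[nz + dd] + g[nz]
      g <- g2
    }
    s <- seq_along(g) - 1L
    dev <- abs(s - 2 * mu)
    obs <- abs(2 * v - 2 * mu)
    p <- sum(g[dev >= obs - 1e-9]) / sum(g)
  } else {
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  comparison_result(v, min(p, 1), "wilcoxon_signed_rank", length(x))
}

# pull a per-slide quantity out of a list of slide_summary objects
summary_values <- function(summaries, population = NULL, field = NULL) {
  if (is.numeric(summaries)) return(summaries)
  stopifnot(all(vapply(summaries, inherits, logical(1), "slide_summary")))
  if (!is.null(population)) {
    vapply(summaries, function(s) s$fractions[[population]], numeric(1))
  } else {
    vapply(summaries, function(s) s[[field]], numeric(1))
  }
}

#' Compare one population's fraction between two groups of slides
#'
#' Unpaired comparisons use the exact Wilcoxon rank-sum test (normal
#' approximation beyond 20 per group); paired comparisons the exact
#' signed-rank test (beyond 25 pairs, normal), with the paired t-test
#' offered alongside because on very small paired samples (n = 3) a rank
#' test cannot reach conventional significance.
#'
#' @param group_a,group_b lists of [summarize_slide()] summaries (or plain
#'   numeric vectors of fractions). Paired comparisons require matched
#'   `slide_id`/`patient_id` order and equal lengths.
#' @param population population index 1-4 (order of [population_levels()])
#'   or label.
#' @param paired logical.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return [comparison_result].
#' @export
compare_fractions <- function(group_a, group_b, population = 1L,
                              paired = FALSE, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (is.character(population)) {
    population <- match(population, population_levels())
  }
  a <- summary_values(group_a, population = population)
  b <- summary_values(group_b, population = population)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 summaries per group")
  }
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal group sizes with matched ids")
  }
  if (test == "t") {
    ht <- stats::t.test(a, b, paired = paired)
    return(comparison_result(ht$statistic, ht$p.value,
                             if (paired) "paired_t" else "t",
                             if (paired) length(a) else c(length(a), length(b))))
  }
  if (paired) wilcoxon_signed_rank(a, b) else wilcoxon_rank_sum(a, b)
}

#' Chi-square homogeneity test of pooled population counts
#'
#' 2 x 4 chi-square test (df 3 when all four populations are represented).
#' Populations empty in both groups are collapsed out with a warning.
#'
#' @param counts_a,counts_b nonnegative integer 4-vectors of pooled cell
#'   counts in [population_levels()] order.
#' @return [comparison_result] with test_name `"chi_square"`.
#' @export
compare_pooled_counts <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b),
            all(counts_a >= 0), all(counts_b >= 0))
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    stop("both groups must have positive totals")
  }
  tab <- rbind(a = counts_a, b = counts_b)
  empty <- colSums(tab) == 0
  if (any(empty)) {
    warning(sum(empty), " zero-margin population(s) collapsed out")
    tab <- tab[, !empty, drop = FALSE]
  }
  if (ncol(tab) < 2L) {
    return(comparison_result(0, 1, "chi_square", rowSums(tab)))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  comparison_result(ht$statistic, ht$p.value, "chi_square",
                    rowSums(tab))
}

#' Linear regression of CD8 infiltrate on Shannon diversity
#'
#' Ordinary least squares of per-montage CD8 counts on the Shannon index
#' across slides, with the two-sided t-test on the slope and a pointwise
#' 95% confidence band for plotting.
#'
#' @param summaries list of [summarize_slide()] summaries.
#' @param stratum `"all"` or a timepoint label to subset on (e.g.
#'   `"primary"`, `"metastasis"`).
#' @param band_points number of grid points for the confidence band.
#' @return list: slope, intercept, r (Pearson), p_value, n, band
#'   (data.frame shannon, fit, lwr, upr), fit (the `lm` object);
#'   `undefined = TRUE` with NA slope when the predictor is constant.
#' @export
diversity_cd8_regression <- function(summaries, stratum = "all",
                                     band_points = 50L) {
  if (stratum != "all") {
    summaries <- Filter(function(s) identical(s$timepoint, stratum),
                        summaries)
  }
  h <- summary_values(summaries, field = "shannon")
  cd8 <- summary_values(summaries, field = "cd8_per_montage")
  keep <- is.finite(h) & is.finite(cd8)
  h <- h[keep]; cd8 <- cd8[keep]
  if (length(h) < 3L) stop("need at least 3 slides in stratum")
  if (stats::sd(h) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p_value = NA_real_, n = length(h), band = NULL,
                fit = NULL, undefined = TRUE))
  }
  fit <- stats::lm(cd8 ~ h)
  co <- summary(fit)$coefficients
  grid <- data.frame(h = seq(min(h), max(h), length.out = band_points))
  ci <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
  list(slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
       r = stats::cor(h, cd8), p_value = unname(co[2, 4]), n = length(h),
       band = data.frame(shannon = grid$h, fit = ci[, "fit"],
                         lwr = ci[, "lwr"], upr = ci[, "upr"]),
       fit = fit, undefined = FALSE)
}

#' Bin a slide into a topology map of dominant populations
#'
#' Divides the slide's bounding box into square bins and reports per-bin
#' population counts and the dominant label (ties broken toward the
#' lower population index; empty bins carry NA and `n = 0`), plus
#' plot-ready point sets layered by population.
#'
#' @param cells CellRecord data.frame with x, y, population.
#' @param bin_size bin edge length in pixels.
#' @param width,height optional slide extent; defaults to the data range.
#' @return list with `grid` (data.frame: bin_x, bin_y, counts per
#'   population, n, dominant) and `points` (list of data.frames per
#'   population).
#' @export
topology_map <- function(cells, bin_size = 64, width = NULL, height = NULL) {
  stopifnot(nrow(cells) > 0, all(c("x", "y", "population") %in% names(cells)))
  w <- if (is.null(width)) max(cells$x) + 1 else width
  h <- if (is.null(height)) max(cells$y) + 1 else height
  nx <- max(1L, ceiling(w / bin_size))
  ny <- max(1L, ceiling(h / bin_size))
  bx <- pmin(nx, 1L + floor(cells$x / bin_size))
  by <- pmin(ny, 1L + floor(cells$y / bin_size))
  pop <- factor(cells$population, levels = population_levels())
  grid <- expand.grid(bin_x = seq_len(nx), bin_y = seq_len(ny))
  counts <- matrix(0L, nrow(grid), 4L,
                   dimnames = list(NULL, population_levels()))
  bin_id <- (by - 1L) * nx + bx
  for (k in 1:4) {
    t_k <- tabulate(bin_id[as.integer(pop) == k], nbins = nx * ny)
    counts[, k] <- t_k
  }
  n <- rowSums(counts)
  dominant <- ifelse(n == 0L, NA_character_,
                     population_levels()[max.col(counts, ties.method = "first")])
  grid <- cbind(grid, as.data.frame(counts), n = n, dominant = dominant)
  pts <- split(cells[, c("x", "y")], pop)
  list(grid = grid, points = pts, bin_size = bin_size)
}
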