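# Shannon entropy, exact Wilcoxon tests vs enumeration, chi-square,
# regression and topology maps

test_that("shannon entropy matches closed forms and brute force", {
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), log(2), tolerance = 1e-12)
  expect_equal(shannon_entropy(rep(0.25, 4), base = 2), 2, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    p <- rgamma(4, 1); p <- p / sum(p)
    brute <- -sum(ifelse(p > 0, p * log(p), 0))
    expect_equal(shannon_entropy(p), brute, tolerance = 1e-12)
    # label-permutation invariance
    expect_equal(shannon_entropy(sample(p)), shannon_entropy(p),
                 tolerance = 1e-12)
    expect_true(shannon_entropy(p) >= 0 && shannon_entropy(p) <= log(4) + 1e-12)
  }
})

test_that("summarize_slide conserves counts and handles montages", {
  sp <- slide_spec(n_cells = 200, fractions = c(0.4, 0.3, 0.2, 0.1),
                   width = 1024, height = 1024, seed = 37)
  tab <- generate_cell_table(sp, include_infiltrate = TRUE)
  montage <- 1L + (tab$x > 512) + 2L * (tab$y > 512)
  s <- summarize_slide(tab, montages = montage, slide_id = "s1",
                       timepoint = "baseline")
  expect_equal(sum(s$fractions) * s$n_cells, 200)
  expect_equal(s$n_cells, 200L)
  expect_equal(s$cd8_per_montage,
               mean(tapply(tab$cd8, montage, sum)))
  expect_equal(s$gzmb_fraction, sum(tab$gzmb & tab$cd8) / sum(tab$cd8))
  empty <- summarize_slide(tab[0, ])
  expect_true(empty$undefined)
})

# independent oracle: enumerate every assignment of pooled values to group
# a (by index combinations), midrank the pooled sample once
rank_sum_oracle <- function(x, y) {
  r <- rank(c(x, y))
  na <- length(x); n <- length(r)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combos <- combn(n, na)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

test_that("exact rank-sum equals enumeration for total n <= 12", {
  set.seed(11)
  cases <- list(
    list(x = c(1.2, 3.4, 2.2), y = c(0.1, 5.5, 6.1)),
    list(x = rnorm(4), y = rnorm(5)),
    list(x = c(1, 1, 2, 3), y = c(1, 2, 2, 4)),           # ties
    list(x = rpois(6, 3), y = rpois(6, 5)),               # heavy ties
    list(x = rnorm(2), y = rnorm(6))
  )
  for (cs in cases) {
    got <- wilcoxon_rank_sum(cs$x, cs$y)
    expect_equal(got$p_value, rank_sum_oracle(cs$x, cs$y),
                 tolerance = 1e-12)
  }
  # tie-free case agrees with stats::wilcox.test exact p
  x <- c(0.3, 1.7, 2.9, 4.1); y <- c(0.9, 2.3, 3.6, 5.2, 6.4)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

# independent oracle for the signed-rank test: enumerate all sign patterns
signed_rank_oracle <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  m <- length(d)
  vs <- vapply(0:(2^m - 1), function(code) {
    signs <- as.integer(intToBits(code))[1:m] == 1L
    sum(r[signs])
  }, numeric(1))
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

test_that("exact signed-rank equals enumeration, incl. the 3-pair case", {
  # all three differences positive: two-sided p = 2/8
  x <- c(5, 6, 7); y <- c(1, 2, 3)
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$p_value, 0.25)
  expect_equal(got$p_value, signed_rank_oracle(x, y))
  set.seed(13)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.3)
    expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                 signed_rank_oracle(a, b), tolerance = 1e-12)
  }
  # ties in |d|
  a <- c(1, 2, 3, 4, 10); b <- c(2, 1, 5, 2, 6)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, signed_rank_oracle(a, b),
               tolerance = 1e-12)
})

test_that("compare_fractions dispatches tests and validates pairing", {
  ga <- lapply(1:5, function(i) mk_summary(c(0.4, 0.3, 0.2, 0.1) + 0.01 * i -
                                             0.03))
  gb <- lapply(1:5, function(i) mk_summary(c(0.1, 0.2, 0.3, 0.4)))
  res <- compare_fractions(ga, gb, population = 1)
  expect_identical(res$test_name, "wilcoxon_rank_sum")
  expect_lt(res$p_value, 0.05)
  # identical groups -> p = 1
  same <- compare_fractions(gb, gb, population = 2)
  expect_equal(same$p_value, 1)
  # paired t alternative
  pt <- compare_fractions(ga, gb, population = 1, paired = TRUE, test = "t")
  expect_identical(pt$test_name, "paired_t")
  expect_error(compare_fractions(ga[1:3], gb, population = 1, paired = TRUE),
               "equal group sizes")
  expect_error(compare_fractions(ga[1], gb[1], population = 1), "at least 2")
})

test_that("pooled chi-square matches a hand calculation", {
  a <- c(30, 20, 10, 40)
  b <- c(10, 25, 30, 35)
  # textbook statistic computed directly from expected counts
  tab <- rbind(a, b)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  res <- compare_pooled_counts(a, b)
  expect_equal(res$statistic, x2, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(x2, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(compare_pooled_counts(a, a)$statistic, 0)
  expect_equal(compare_pooled_counts(a, a)$p_value, 1)
  # extreme separation (two empty populations collapse, hence the warning)
  expect_lt(suppressWarnings(compare_pooled_counts(c(100, 0, 0, 0),
                                                   c(0, 100, 0, 0)))$p_value,
            1e-10)
  expect_warning(compare_pooled_counts(c(10, 0, 5, 5), c(20, 0, 5, 5)),
                 "collapsed")
})

test_that("diversity_cd8_regression recovers exact and planted relations", {
  # exact line
  ex <- lapply(1:6, function(i) {
    s <- mk_summary(rep(0.25, 4))
    s$shannon <- i / 5
    s$cd8_per_montage <- 2 * s$shannon + 1
    s
  })
  fit <- suppressWarnings(diversity_cd8_regression(ex))  # perfect fit
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_true(all(fit$band$lwr <= fit$band$fit & fit$band$fit <= fit$band$upr))
  # constant predictor flagged undefined
  con <- lapply(1:4, function(i) mk_summary(rep(0.25, 4), cd8 = i))
  expect_true(diversity_cd8_regression(con)$undefined)
  # stratum filter
  mix <- c(lapply(1:4, function(i) {
    s <- mk_summary(rep(0.25, 4), cd8 = i, timepoint = "metastasis")
    s$shannon <- i / 4
    s
  }), ex)
  expect_equal(suppressWarnings(
    diversity_cd8_regression(mix, stratum = "metastasis"))$n, 4L)
})

test_that("planted negative association is detected reliably", {
  hits <- 0L
  n_rep <- 60L
  for (rep_i in seq_len(n_rep)) {
    set.seed(1000 + rep_i)
    h <- runif(30, 0, log(4))
    cd8 <- 40 - 12 * h + rnorm(30, 0, sqrt((12^2 * var(h)) *
                                             (1 - 0.7^2) / 0.7^2))
    sums <- lapply(seq_along(h), function(i) {
      s <- mk_summary(rep(0.25, 4), cd8 = cd8[i])
      s$shannon <- h[i]
      s
    })
    fit <- diversity_cd8_regression(sums)
    if (fit$slope < 0 && fit$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("topology_map bins cells, marks empties, recovers clusters", {
  sp <- slide_spec(n_cells = 300, fractions = rep(0.25, 4), seed = 41,
                   width = 1200, height = 1200, clustering = 8)
  tab <- generate_cell_table(sp)
  tm <- topology_map(tab, bin_size = 100, width = 1200, height = 1200)
  expect_equal(sum(tm$grid$n), 300)
  expect_true(all(is.na(tm$grid$dominant[tm$grid$n == 0])))
  # dominant label matches the plurality of truth labels in occupied bins
  occ <- tm$grid[tm$grid$n > 0, ]
  agree <- vapply(seq_len(nrow(occ)), function(i) {
    inbin <- tab$x >= (occ$bin_x[i] - 1) * 100 & tab$x < occ$bin_x[i] * 100 &
      tab$y >= (occ$bin_y[i] - 1) * 100 & tab$y < occ$bin_y[i] * 100
    cnt <- table(tab$population[inbin])
    occ$dominant[i] %in% names(cnt)[cnt == max(cnt)]
  }, logical(1))
  expect_gte(mean(agree), 0.9)
  # uniform slide: dominant-label excess within multinomial bounds
  spu <- slide_spec(n_cells = 400, fractions = rep(0.25, 4), seed = 43,
                    width = 1200, height = 1200)
  tabu <- generate_cell_table(spu)
  tmu <- topology_map(tabu, bin_size = 300, width = 1200, height = 1200)
  occu <- tmu$grid[tmu$grid$n > 0, ]
  mx <- apply(as.matrix(occu[, population_levels()]), 1, max)
  # simulation oracle: 99.9% quantile of the multinomial max per bin size
  set.seed(7)
  crit <- vapply(occu$n, function(n) {
    sims <- apply(rmultinom(2000, n, rep(0.25, 4)), 2, max)
    quantile(sims, 0.999)
  }, numeric(1))
  expect_true(all(mx <= crit))
})
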