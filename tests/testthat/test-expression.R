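# QC filter, TPM conversion, gene/signature tests, enrichment

test_that("qc_filter drops sub-threshold samples and logs them", {
  set.seed(5)
  counts <- matrix(rpois(20 * 13, 50), 20, 13,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("S%02d", 1:13)))
  samples <- data.frame(sample_id = colnames(counts),
                        timepoint = "baseline",
                        tumor_fraction = c(0.1, 0.1, runif(11, 0.3, 0.9)))
  out <- qc_filter(counts, samples)
  expect_equal(ncol(out$counts), 11L)
  expect_equal(nrow(out$excluded), 2L)
  expect_setequal(out$excluded$sample_id, c("S01", "S02"))
  # boundary: exactly at threshold retained (strict <)
  samples$tumor_fraction[1] <- 0.20
  expect_equal(ncol(qc_filter(counts, samples)$counts), 12L)
  # threshold 0 is the identity
  expect_equal(ncol(qc_filter(counts, samples, 0)$counts), 13L)
  samples$tumor_fraction <- 0.01
  expect_error(qc_filter(counts, samples), "every sample")
})

test_that("to_tpm matches hand calculations and conserves column sums", {
  # single gene: all mass
  m1 <- matrix(c(7, 700), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_true(all(to_tpm(m1, c(g1 = 2)) == 1e6))
  # two genes, equal counts, lengths 1 and 2 kb
  m2 <- matrix(c(100, 100), 2, 1, dimnames = list(c("g1", "g2"), "a"))
  tpm2 <- to_tpm(m2, c(g1 = 1, g2 = 2))
  expect_equal(as.numeric(tpm2), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # random matrices: columns sum to 1e6
  set.seed(2)
  m <- matrix(rpois(300, 30), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  tpm <- to_tpm(m, setNames(runif(30, 0.5, 5), rownames(m)))
  expect_equal(colSums(tpm), rep(1e6, 10), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_warning(to_tpm(cbind(m, zero = 0L),
                        setNames(runif(30, 0.5, 5), rownames(m))),
                 "zero-total")
})

test_that("gene_test matches a hand-computed Welch t on a 3v3 toy table", {
  tpm <- rbind(GENEX = c(8, 10, 12, 3, 4, 5),
               OTHER = c(5, 5, 5, 5, 5, 5))
  colnames(tpm) <- sprintf("S%02d", 1:6)
  samples <- mk_samples(3, 3)
  res <- gene_test(tpm, "GENEX", samples)
  x <- log2(tpm["GENEX", 1:3] + 1); y <- log2(tpm["GENEX", 4:6] + 1)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  expect_identical(res$direction, "down")
  # identical groups: p = 1, difference 0
  null <- gene_test(tpm, "OTHER", samples)
  expect_equal(null$p_value, 1)
  expect_equal(null$log2_fc, 0)
  expect_error(gene_test(tpm, "MISSING", samples), "MISSING")
})

test_that("gene_test and signature scores are order-invariant", {
  spec <- expression_spec(n_genes = 80, n_pre = 6, n_post = 6,
                          target_effect = -1, seed = 17)
  out <- generate_expression(spec)
  tpm <- to_tpm(out$counts, out$gene_lengths)
  res1 <- gene_test(tpm, "SOCS3", out$samples)
  perm <- sample(ncol(tpm))
  res2 <- gene_test(tpm[sample(nrow(tpm)), perm], "SOCS3", out$samples)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-12)
  sc1 <- signature_score(tpm, c("SOCS3", "MYC", "JUNB"))
  sc2 <- signature_score(tpm[sample(nrow(tpm)), ], c("JUNB", "SOCS3", "MYC"))
  expect_equal(sc1$score, sc2$score, tolerance = 1e-12)
})

test_that("signature scores center at zero and flag poor coverage", {
  spec <- expression_spec(n_genes = 60, n_pre = 5, n_post = 5, seed = 19)
  out <- generate_expression(spec)
  tpm <- to_tpm(out$counts, out$gene_lengths)
  sc <- signature_score(tpm, default_signatures()[[1]], "sigA")
  expect_equal(mean(sc$score), 0, tolerance = 1e-9)
  # constant matrix: degenerate z-scores become 0, flagged via p = 1 path
  const <- matrix(100, 10, 6, dimnames = list(sprintf("G%d", 1:10),
                                              sprintf("S%02d", 1:6)))
  sc0 <- signature_score(const, sprintf("G%d", 1:5))
  expect_true(all(sc0$score == 0))
  # < 50% of genes present -> undefined
  scna <- signature_score(tpm, c("SOCS3", "NOPE1", "NOPE2"))
  expect_true(all(is.na(scna$score)))
  expect_true(attr(scna, "undefined"))
  expect_error(signature_test(scna, out$samples), "undefined")
})

test_that("planted suppression is detected at the rate an oracle predicts", {
  # route 1: full pipeline detection rate on generated data
  detected_gene <- 0L
  lower_sig <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    spec <- expression_spec(n_genes = 1000, n_pre = 10, n_post = 10,
                            target_effect = -1, dispersion = 0.2,
                            seed = 5000 + i)
    out <- generate_expression(spec)
    tpm <- to_tpm(out$counts, out$gene_lengths)
    gt <- gene_test(tpm, "SOCS3", out$samples)
    if (gt$p_value < 0.05 && gt$direction == "down") {
      detected_gene <- detected_gene + 1L
    }
    sc <- signature_score(tpm, spec$signature_genes[[1]], "A")
    st <- signature_test(sc, out$samples)
    if (st$difference < 0) lower_sig <- lower_sig + 1L
  }
  # route 2 (oracle): Monte-Carlo power of a t-test on log2 NB draws
  # under the same generative assumptions, independent of the package
  # (mu ~ 2^U(3,9), dispersion 0.2, halving post-treatment, ~TPM scale)
  set.seed(424)
  oracle_hits <- 0L
  n_or <- 800L
  for (i in seq_len(n_or)) {
    mu <- 2^runif(1, 3, 9)
    x <- log2(7.5 * rnbinom(10, mu = mu, size = 5) + 1)
    y <- log2(7.5 * rnbinom(10, mu = mu / 2, size = 5) + 1)
    ht <- t.test(x, y)
    if (ht$p.value < 0.05 && mean(y) < mean(x)) {
      oracle_hits <- oracle_hits + 1L
    }
  }
  rate <- detected_gene / n_rep
  oracle <- oracle_hits / n_or
  se <- sqrt(rate * (1 - rate) / n_rep + oracle * (1 - oracle) / n_or)
  expect_lt(abs(rate - oracle), 3 * se + 0.02)
  expect_gte(rate, 0.5)                      # basic power floor
  expect_gte(lower_sig / n_rep, 0.95)        # signature direction recovery
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- sprintf("g%02d", 1:20)
  de <- universe[1:4]
  sets <- list(hit = c(universe[c(1, 2, 3)], universe[10:11]),
               miss = universe[15:19],
               ident = de)
  res <- gene_set_enrichment(de, universe, sets)
  # hand calculation: overlap 3 of set 5, universe 20, de 4
  p_hand <- (choose(5, 3) * choose(15, 1) + choose(5, 4)) / choose(20, 4)
  expect_equal(res$p_value[res$set == "hit"], p_hand, tolerance = 1e-12)
  expect_lt(res$p_value[res$set == "ident"],
            res$p_value[res$set == "miss"])
  # disjoint set -> p = 1
  expect_equal(res$p_value[res$set == "miss"], 1)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_error(gene_set_enrichment(de, character(), sets), "universe")
  expect_error(gene_set_enrichment(c(de, "zz"), universe, sets), "within")
})

test_that("GMT files round-trip and ship with the package", {
  sets <- list(a = c("x", "y"), b = c("z"))
  tmp <- tempfile(fileext = ".gmt")
  write_gmt(sets, tmp)
  expect_equal(read_gmt(tmp), sets)
  sigs <- default_signatures()
  expect_length(sigs, 2L)
  expect_true(all(lengths(sigs) >= 5))
})
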