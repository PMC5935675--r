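# Transcriptional pharmacodynamics: tumor-content QC, TPM conversion,
# pre/post gene and signature tests, and gene-set overrepresentation.

#' Filter samples by tumor content
#'
#' Removes samples whose tumor fraction is strictly below the threshold
#' (a sample exactly at the threshold is retained).
#'
#' @param counts genes x samples matrix.
#' @param samples sample sheet with sample_id and tumor_fraction covering
#'   all columns of `counts`.
#' @param min_tumor_fraction exclusion threshold (default 0.20).
#' @return list: counts, samples (filtered), excluded (data.frame of
#'   dropped samples with their fractions).
#' @export
qc_filter <- function(counts, samples, min_tumor_fraction = 0.20) {
  stopifnot(is.matrix(counts), all(colnames(counts) %in% samples$sample_id))
  sm <- samples[match(colnames(counts), samples$sample_id), ]
  drop <- sm$tumor_fraction < min_tumor_fraction
  if (all(drop)) stop("tumor-content QC removed every sample")
  excluded <- sm[drop, c("sample_id", "tumor_fraction")]
  rownames(excluded) <- NULL
  list(counts = counts[, !drop, drop = FALSE],
       samples = sm[!drop, , drop = FALSE],
       excluded = excluded)
}

#' Convert counts to transcripts per million
#'
#' `tpm = (count / length_kb) / sum(count / length_kb) * 1e6` per sample;
#' every column sums to 1e6. A zero-total sample yields NA with a warning.
#'
#' @param counts genes x samples matrix of nonnegative counts.
#' @param gene_lengths per-gene effective lengths in kb, named or in row
#'   order.
#' @return TPM matrix of the same shape.
#' @export
to_tpm <- function(counts, gene_lengths) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    if (!all(rownames(counts) %in% names(gene_lengths))) {
      stop("gene_lengths missing for some genes")
    }
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
  rate <- counts / gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("zero-total sample(s): TPM undefined (NA)")
    tot[tot == 0] <- NA_real_
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Pre/post test for a single gene
#'
#' Two-sample (or paired) t-test on `log2(TPM + pseudocount)` between the
#' two timepoints.
#'
#' @param tpm TPM matrix.
#' @param gene gene name (row).
#' @param samples sample sheet with sample_id and timepoint.
#' @param groups length-2 character, reference then treated timepoint.
#' @param paired logical; paired requires matched patient order.
#' @param pseudocount added before log2.
#' @return [comparison_result] with extra fields `log2_fc` (treated minus
#'   reference mean log2 expression) and `direction`.
#' @export
gene_test <- function(tpm, gene, samples, groups = c("baseline", "cycle2"),
                      paired = FALSE, pseudocount = 1) {
  if (!gene %in% rownames(tpm)) {
    stop("gene not found in expression matrix: ", gene)
  }
  sm <- samples[match(colnames(tpm), samples$sample_id), ]
  x <- log2(tpm[gene, sm$timepoint == groups[1]] + pseudocount)
  y <- log2(tpm[gene, sm$timepoint == groups[2]] + pseudocount)
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 samples per group")
  res <- gene_values_test(x, y, paired)
  res$log2_fc <- mean(y) - mean(x)
  res$direction <- if (res$log2_fc < 0) "down" else "up"
  res
}

gene_values_test <- function(x, y, paired = FALSE) {
  if (stats::sd(c(x, y)) == 0) {
    return(comparison_result(0, 1, if (paired) "paired_t" else "t",
                             c(length(x), length(y))))
  }
  ht <- stats::t.test(x, y, paired = paired)
  comparison_result(ht$statistic, ht$p.value,
                    if (paired) "paired_t" else "t",
                    c(length(x), length(y)))
}

#' Per-sample signature score
#'
#' Mean over signature genes of the per-gene z-score of
#' `log2(TPM + pseudocount)` across samples. Genes with zero variance
#' contribute 0. If fewer than `min_coverage` of the signature genes are
#' present the score is undefined (all NA, flagged).
#'
#' @param tpm TPM matrix.
#' @param signature character vector of gene names.
#' @param signature_name label carried into the result.
#' @param min_coverage minimum fraction of signature genes present (0.5).
#' @param pseudocount added before log2.
#' @return data.frame: sample_id, signature_name, score; attribute
#'   `coverage` gives the fraction of genes found.
#' @export
signature_score <- function(tpm, signature, signature_name = "signature",
                            min_coverage = 0.5, pseudocount = 1) {
  present <- intersect(signature, rownames(tpm))
  coverage <- length(present) / length(signature)
  if (coverage < min_coverage) {
    out <- data.frame(sample_id = colnames(tpm),
                      signature_name = signature_name, score = NA_real_)
    attr(out, "coverage") <- coverage
    attr(out, "undefined") <- TRUE
    return(out)
  }
  lx <- log2(tpm[present, , drop = FALSE] + pseudocount)
  mu <- rowMeans(lx)
  sdv <- apply(lx, 1L, stats::sd)
  z <- (lx - mu) / ifelse(sdv == 0, Inf, sdv)  # zero-variance gene -> 0
  out <- data.frame(sample_id = colnames(tpm),
                    signature_name = signature_name,
                    score = colMeans(z))
  rownames(out) <- NULL
  attr(out, "coverage") <- coverage
  attr(out, "undefined") <- FALSE
  out
}

#' Pre/post test of a signature score
#'
#' @param scores data.frame from [signature_score()].
#' @param samples sample sheet with sample_id and timepoint.
#' @param groups length-2 character, reference then treated timepoint.
#' @param paired logical.
#' @return [comparison_result] with `difference` (treated minus reference
#'   mean score).
#' @export
signature_test <- function(scores, samples,
                           groups = c("baseline", "cycle2"),
                           paired = FALSE) {
  sm <- samples[match(scores$sample_id, samples$sample_id), ]
  x <- scores$score[sm$timepoint == groups[1]]
  y <- scores$score[sm$timepoint == groups[2]]
  if (anyNA(c(x, y))) stop("undefined signature scores")
  res <- gene_values_test(x, y, paired)
  res$difference <- mean(y) - mean(x)
  res
}

#' Hypergeometric gene-set overrepresentation
#'
#' One-sided hypergeometric tail per set (probability of at least the
#' observed overlap between the differential genes and the set within the
#' universe), with Benjamini-Hochberg adjustment across sets.
#'
#' @param de_genes differential gene names (subset of `universe`).
#' @param universe all tested gene names.
#' @param sets named list of gene sets (intersected with the universe).
#' @return data.frame: set, set_size, overlap, p_value, q_value.
#' @export
gene_set_enrichment <- function(de_genes, universe, sets) {
  if (!length(universe)) stop("empty universe")
  if (!all(de_genes %in% universe)) stop("de_genes must be within universe")
  if (!length(sets)) stop("no gene sets supplied")
  n_u <- length(unique(universe))
  de <- unique(de_genes)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(de, s))
    p <- if (length(s) == 0L) 1 else {
      stats::phyper(k - 1L, length(s), n_u - length(s), length(de),
                    lower.tail = FALSE)
    }
    data.frame(set = nm, set_size = length(s), overlap = k, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: set name, description, then gene names.
#'
#' @param path file path.
#' @param sets named list of character vectors (for writing).
#' @param description description field written for each set.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
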