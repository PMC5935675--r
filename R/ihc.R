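# pSTAT3 IHC T-scoring, eligibility, and the screening funnel.

#' Compute a pSTAT3 T-score
#'
#' Semi-quantitative additive score in the Allred convention: an intensity
#' component (0-3) plus a proportion component binning the percentage of
#' stained tumor cells (0: 0%; 1: >0-1%; 2: >1-10%; 3: >10-33%;
#' 4: >33-66%; 5: >66-100%). The total (0, 2-8) maps to an interpretive
#' category: 0 negative, 3-4 weak/equivocal, 5-6 moderate, 7-8 high.
#' A total of 1 is unreachable; percent > 0 with intensity 0 is treated as
#' no staining (total 0) with a warning, since intensity 0 means unstained.
#'
#' @param percent_positive percent of stained cells, in [0, 100].
#' @param intensity staining intensity, ordinal 0-3.
#' @param proportion_edges upper bin edges of the proportion score
#'   (defaults to the Allred cut points 0, 1, 10, 33, 66, 100).
#' @return object of class `tscore`: list with intensity_score,
#'   proportion_score, total, category.
#' @export
tscore <- function(percent_positive, intensity,
                   proportion_edges = c(0, 1, 10, 33, 66, 100)) {
  if (!is.numeric(percent_positive) || length(percent_positive) != 1L ||
      is.na(percent_positive) || percent_positive < 0 ||
      percent_positive > 100) {
    stop("`percent_positive` must be a single value in [0, 100]")
  }
  if (!intensity %in% 0:3) stop("`intensity` must be in {0, 1, 2, 3}")
  prop <- if (percent_positive == 0) 0L else {
    as.integer(findInterval(percent_positive, proportion_edges,
                            left.open = TRUE))
  }
  prop <- min(prop, 5L)
  intensity <- as.integer(intensity)
  if (prop == 0L || intensity == 0L) {
    if (prop > 0L && intensity == 0L) {
      warning("percent > 0 with intensity 0: scored as total 0 (no staining)")
    }
    total <- 0L
  } else {
    total <- prop + intensity
  }
  structure(list(intensity_score = intensity, proportion_score = prop,
                 total = total, category = tscore_category(total)),
            class = "tscore")
}

# interpretive anchors: 0 negative; 3-4 weak/equivocal; 5-6 moderate; >6 high
tscore_category <- function(total) {
  stopifnot(total %in% c(0L, 2:8))
  if (total == 0L) "negative"
  else if (total <= 4L) "weak/equivocal"
  else if (total <= 6L) "moderate"
  else "high"
}

#' @export
print.tscore <- function(x, ...) {
  cat(sprintf("pSTAT3 T-score: %d (intensity %d + proportion %d) -> %s\n",
              x$total, x$intensity_score, x$proportion_score, x$category))
  invisible(x)
}

#' Trial eligibility from a T-score
#'
#' Eligible when the interpretive category is moderate or high, i.e. total
#' score at or above the threshold (default 5, the moderate anchor).
#'
#' @param t a [tscore()] object.
#' @param threshold minimum total score; default 5.
#' @return logical.
#' @export
is_eligible <- function(t, threshold = 5L) {
  stopifnot(inherits(t, "tscore"))
  t$total >= threshold
}

#' Summarize a pSTAT3 screening funnel
#'
#' Counts screened tumors by interpretive category group and reports the
#' positive (moderate or high) fraction among tumors with a result.
#'
#' @param results list of [tscore()] objects, or a character vector of
#'   categories (`"negative"`, `"weak/equivocal"`, `"moderate"`, `"high"`).
#' @param n_consented number of consented patients (>= number of results).
#' @return object of class `screening_funnel`: counts plus
#'   `positive_fraction` (NA when no results) and `positive_percent`
#'   (rounded to one decimal).
#' @export
funnel_summary <- function(results, n_consented) {
  if (is.list(results)) {
    stopifnot(all(vapply(results, inherits, logical(1), "tscore")))
    cats <- vapply(results, function(t) t$category, character(1))
  } else {
    cats <- as.character(results)
  }
  valid <- c("negative", "weak/equivocal", "moderate", "high")
  if (!all(cats %in% valid)) stop("unknown T-score category in `results`")
  n_res <- length(cats)
  if (n_res > n_consented) stop("more results than consented patients")
  n_pos <- sum(cats %in% c("moderate", "high"))
  n_weak <- sum(cats == "weak/equivocal")
  n_neg <- sum(cats == "negative")
  frac <- if (n_res > 0) n_pos / n_res else NA_real_
  structure(list(n_consented = as.integer(n_consented),
                 n_with_result = n_res,
                 n_high_moderate = n_pos, n_weak = n_weak, n_negative = n_neg,
                 positive_fraction = frac,
                 positive_percent = round(100 * frac, 1)),
            class = "screening_funnel")
}

#' @export
print.screening_funnel <- function(x, ...) {
  cat(sprintf(
    "Screened %d consented; %d with result: %d moderate/high (%.1f%%), %d weak, %d negative\n",
    x$n_consented, x$n_with_result, x$n_high_moderate,
    x$positive_percent, x$n_weak, x$n_negative))
  invisible(x)
}

#' Score an IHC results file
#'
#' Reads a CSV with columns sample_id, percent_positive, intensity and
#' writes (or returns) per-sample scores and eligibility.
#'
#' @param infile input CSV path.
#' @param outfile optional output CSV path.
#' @param threshold eligibility threshold passed to [is_eligible()].
#' @return invisibly, the scored data.frame (sample_id, proportion_score,
#'   intensity_score, total, category, eligible).
#' @export
score_ihc_file <- function(infile, outfile = NULL, threshold = 5L) {
  d <- utils::read.csv(infile, stringsAsFactors = FALSE)
  need <- c("sample_id", "percent_positive", "intensity")
  if (!all(need %in% names(d))) {
    stop("input must have columns: ", paste(need, collapse = ", "))
  }
  scored <- lapply(seq_len(nrow(d)),
                   function(i) tscore(d$percent_positive[i], d$intensity[i]))
  out <- data.frame(
    sample_id = d$sample_id,
    proportion_score = vapply(scored, `[[`, integer(1), "proportion_score"),
    intensity_score = vapply(scored, `[[`, integer(1), "intensity_score"),
    total = vapply(scored, `[[`, integer(1), "total"),
    category = vapply(scored, `[[`, character(1), "category"),
    eligible = vapply(scored, is_eligible, logical(1), threshold = threshold))
  if (!is.null(outfile)) utils::write.csv(out, outfile, row.names = FALSE)
  invisible(out)
}
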