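# shared helpers: truth matching for image pipelines and tiny builders

# match called cells to ground-truth cells by nearest centroid
match_to_truth <- function(calls, truth) {
  idx <- vapply(seq_len(nrow(calls)), function(i) {
    which.min((truth$x - calls$x[i])^2 + (truth$y - calls$y[i])^2)
  }, integer(1))
  data.frame(call = seq_len(nrow(calls)), truth = idx,
             dist = sqrt((truth$x[idx] - calls$x)^2 +
                           (truth$y[idx] - calls$y)^2))
}

# minimal slide_summary builder for statistics tests
mk_summary <- function(fractions, cd8 = NA_real_, timepoint = "primary",
                       slide_id = "s") {
  structure(list(slide_id = slide_id, timepoint = timepoint,
                 n_cells = 100L,
                 fractions = stats::setNames(fractions, population_levels()),
                 shannon = shannon_entropy(fractions),
                 cd8_per_montage = cd8, gzmb_fraction = NA_real_,
                 undefined = FALSE),
            class = "slide_summary")
}

# sample sheet helper for expression tests
mk_samples <- function(n_pre, n_post, tumor_fraction = 0.8) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n_pre + n_post)),
             patient_id = sprintf("P%02d", seq_len(n_pre + n_post)),
             timepoint = rep(c("baseline", "cycle2"), c(n_pre, n_post)),
             tumor_fraction = tumor_fraction)
}
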