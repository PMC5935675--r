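# RECIST-level endpoint summaries: response rates, Kaplan-Meier medians
# with confidence intervals, and adverse-event tabulation.

#' Best-response summary of a treated cohort
#'
#' ORR = (CR + PR) / n over all treated patients (unevaluable patients stay
#' in the denominator); the clinical benefit rate counts CR, PR and SD
#' lasting more than 24 weeks. Display percentages are rounded to integer
#' precision (round-half-to-even); exact fractions are retained.
#'
#' @param cohort a `trial_cohort` (from [generate_cohort()]) or a
#'   data.frame with best_response and optional sd_duration_weeks.
#' @return object of class `response_summary`: counts by category, n, and
#'   for each of ORR / SD rate / CBR both the exact fraction and the
#'   integer display percent.
#' @export
response_summary <- function(cohort) {
  pts <- if (inherits(cohort, "trial_cohort")) cohort$patients else cohort
  if (nrow(pts) == 0L) stop("empty cohort")
  valid <- c("CR", "PR", "SD", "PD", "NE")
  if (!all(pts$best_response %in% valid)) {
    stop("best_response must be one of ", paste(valid, collapse = ", "))
  }
  n <- nrow(pts)
  counts <- table(factor(pts$best_response, levels = valid))
  orr <- unname(counts["CR"] + counts["PR"]) / n
  sd_rate <- unname(counts["SD"]) / n
  sd_dur <- if ("sd_duration_weeks" %in% names(pts)) {
    pts$sd_duration_weeks
  } else {
    rep(NA_real_, n)
  }
  cbr_n <- sum(pts$best_response %in% c("CR", "PR")) +
    sum(pts$best_response == "SD" & !is.na(sd_dur) & sd_dur > 24)
  structure(list(n = n, counts = counts,
                 orr = orr, orr_percent = round(100 * orr),
                 sd_rate = sd_rate, sd_percent = round(100 * sd_rate),
                 cbr = cbr_n / n, cbr_percent = round(100 * cbr_n / n)),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("n = %d: ", x$n))
  cat(paste(sprintf("%s %d", names(x$counts), as.integer(x$counts)),
            collapse = ", "), "\n")
  cat(sprintf("ORR %d%% (%.3f), SD %d%% (%.3f), CBR %d%% (%.3f)\n",
              x$orr_percent, x$orr, x$sd_percent, x$sd_rate,
              x$cbr_percent, x$cbr))
  invisible(x)
}

#' Kaplan-Meier median with confidence interval
#'
#' Product-limit estimate; the median is the first time the survival curve
#' drops to 0.5 or below, with a 95% CI from the log-log transformed
#' curve (Brookmeyer-Crowley-style inversion, the `survival` package
#' default machinery). With no events the median is undefined.
#'
#' @param times follow-up times (> 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @param conf_type CI transform: `"log-log"` (default), `"log"`, or
#'   `"plain"`.
#' @return object of class `km_estimate`: median, ci_low, ci_high, n,
#'   n_events, undefined flag, and the `survfit` object.
#' @export
km_estimate <- function(times, events, conf_type = c("log-log", "log",
                                                     "plain")) {
  conf_type <- match.arg(conf_type)
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = conf_type)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  structure(list(median = med,
                 ci_low = unname(tab["0.95LCL"]),
                 ci_high = unname(tab["0.95UCL"]),
                 n = length(times), n_events = sum(events),
                 undefined = sum(events) == 0 || is.na(med),
                 fit = fit), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("KM median: undefined (%d events / %d)\n", x$n_events, x$n))
  } else {
    cat(sprintf("KM median %.2f (95%% CI %.2f-%s), %d events / %d\n",
                x$median, x$ci_low,
                ifelse(is.na(x$ci_high), "NA", sprintf("%.2f", x$ci_high)),
                x$n_events, x$n))
  }
  invisible(x)
}

#' Expand per-event grade counts to a long-format AE table
#'
#' Inverse of the tabulation in [ae_table()]: given one row per adverse
#' event with the number of patients at each maximum grade, emits one
#' record per affected patient. Patient identifiers are assigned
#' cyclically over `1:n_patients` within each event (each patient appears
#' at most once per event), so they are synthetic placeholders adequate
#' for max-grade tabulation but carry no cross-event meaning.
#'
#' @param counts data.frame: ae_name, grade1, grade2, grade3, grade4.
#' @param n_patients cohort size; per-event totals must not exceed it.
#' @return long data.frame: patient_id, ae_name, max_grade.
#' @export
ae_counts_to_long <- function(counts, n_patients) {
  stopifnot(all(c("ae_name", paste0("grade", 1:4)) %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    g <- as.integer(counts[i, paste0("grade", 1:4)])
    if (sum(g) > n_patients) {
      stop("per-event total exceeds n_patients for ", counts$ae_name[i])
    }
    if (sum(g) == 0L) return(NULL)
    data.frame(patient_id = seq_len(sum(g)),
               ae_name = counts$ae_name[i],
               max_grade = rep(1:4, g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adverse-event summary table
#'
#' One row per adverse event with per-grade patient counts (each patient
#' counted once per event at their maximum grade) and a total column with
#' integer percent of treated patients. Rows are kept when incidence
#' reaches `min_incidence` or any grade >= 3 event occurred.
#'
#' @param ae long-format data.frame: patient_id, ae_name, max_grade (1-4).
#'   A `trial_cohort` may be passed directly.
#' @param n_patients number of treated patients (the denominator).
#' @param min_incidence incidence threshold (default 0.10).
#' @return data.frame: ae_name, grade1..grade4, total, percent.
#' @export
ae_table <- function(ae, n_patients, min_incidence = 0.10) {
  if (inherits(ae, "trial_cohort")) ae <- ae$ae
  n_patients <- assert_count(n_patients, "n_patients", min = 1L)
  if (nrow(ae) == 0L) {
    return(data.frame(ae_name = character(), grade1 = integer(),
                      grade2 = integer(), grade3 = integer(),
                      grade4 = integer(), total = integer(),
                      percent = numeric()))
  }
  if (!all(ae$max_grade %in% 1:4)) stop("grades must be in 1-4")
  # max grade per patient per event
  key <- paste(ae$patient_id, ae$ae_name, sep = "\r")
  mx <- tapply(ae$max_grade, key, max)
  nm <- vapply(strsplit(names(mx), "\r", fixed = TRUE), `[`, character(1), 2L)
  rows <- lapply(sort(unique(nm)), function(a) {
    g <- tabulate(mx[nm == a], nbins = 4L)
    data.frame(ae_name = a, grade1 = g[1], grade2 = g[2],
               grade3 = g[3], grade4 = g[4], total = sum(g),
               percent = round(100 * sum(g) / n_patients))
  })
  out <- do.call(rbind, rows)
  keep <- out$total / n_patients >= min_incidence |
    (out$grade3 + out$grade4) > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
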