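# Exact operating characteristics of a two-stage single-arm binomial design.
#
# Stage 1 enrolls n1 patients; the study continues only if at least r1
# responses are seen. At full accrual of n_total patients the agent is
# deemed worthy of further study if at least r total responses are observed
# (stage-1 responses count toward the total).

#' Construct a two-stage single-arm binomial design
#'
#' @param n1 stage-1 sample size.
#' @param r1 minimum stage-1 responses required to continue.
#' @param n_total overall sample size (>= n1).
#' @param r minimum total responses to deem the agent worthy.
#' @param p0,p1 null and alternative true response probabilities
#'   (0 <= p0 < p1 <= 1).
#' @return object of class `two_stage_design`.
#' @examples
#' d <- two_stage_design(n1 = 21, r1 = 2, n_total = 41, r = 5,
#'                       p0 = 0.05, p1 = 0.20)
#' operating_characteristics(d)
#' @export
two_stage_design <- function(n1, r1, n_total, r, p0 = 0.05, p1 = 0.20) {
  n1 <- assert_count(n1, "n1", min = 1L)
  n_total <- assert_count(n_total, "n_total", min = 1L)
  r1 <- assert_count(r1, "r1")
  r <- assert_count(r, "r")
  if (n1 > n_total) stop("n1 must be <= n_total")
  if (r1 > n1) stop("r1 must be <= n1")
  if (r < r1 || r > n_total) stop("r must satisfy r1 <= r <= n_total")
  assert_prob(c(p0, p1), "p0/p1")
  if (p0 >= p1) stop("p0 must be < p1")
  structure(list(n1 = n1, r1 = r1, n_total = n_total, r = r,
                 p0 = p0, p1 = p1),
            class = "two_stage_design")
}

#' Exact probability of deeming the agent worthy
#'
#' Probability, at true response rate `p`, that the design passes both
#' gates: at least `r1` responses among the first `n1` patients and at
#' least `r` responses overall. Computed by exact summation over stage-1
#' outcomes times binomial tail probabilities for stage 2 — no Monte Carlo.
#'
#' @param d a [two_stage_design()].
#' @param p true response probability.
#' @return probability in [0, 1].
#' @export
reject_probability <- function(d, p) {
  stopifnot(inherits(d, "two_stage_design"))
  assert_prob(p, "p")
  n2 <- d$n_total - d$n1
  total <- 0
  for (x1 in d$r1:d$n1) {
    need <- max(0L, d$r - x1)
    tail2 <- if (need == 0L) 1 else {
      stats::pbinom(need - 1L, n2, p, lower.tail = FALSE)
    }
    total <- total + stats::dbinom(x1, d$n1, p) * tail2
  }
  total
}

#' Exact operating characteristics of a two-stage design
#'
#' @param d a [two_stage_design()].
#' @return object of class `operating_characteristics`: alpha (type I error
#'   at p0), power (at p1), pet0 (probability of early termination under
#'   p0), expected_n0 (expected sample size under p0).
#' @export
operating_characteristics <- function(d) {
  stopifnot(inherits(d, "two_stage_design"))
  pet0 <- if (d$r1 == 0L) 0 else stats::pbinom(d$r1 - 1L, d$n1, d$p0)
  structure(list(
    alpha = reject_probability(d, d$p0),
    power = reject_probability(d, d$p1),
    pet0 = pet0,
    expected_n0 = d$n1 + (1 - pet0) * (d$n_total - d$n1),
    design = d), class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  d <- x$design
  cat(sprintf("Two-stage design: continue if >= %d/%d, worthy if >= %d/%d\n",
              d$r1, d$n1, d$r, d$n_total))
  cat(sprintf("  alpha (p = %.2f): %.4f\n", d$p0, x$alpha))
  cat(sprintf("  power (p = %.2f): %.4f\n", d$p1, x$power))
  cat(sprintf("  PET(p0): %.4f   E[N | p0]: %.2f\n", x$pet0, x$expected_n0))
  invisible(x)
}

#' Interim (stage-1) decision
#'
#' @param x1 responses observed among the first `n1` patients.
#' @param d a [two_stage_design()].
#' @return `"continue"` or `"stop_early"`.
#' @export
interim_decision <- function(x1, d) {
  stopifnot(inherits(d, "two_stage_design"))
  x1 <- assert_count(x1, "x1")
  if (x1 > d$n1) stop("x1 cannot exceed n1")
  if (x1 >= d$r1) "continue" else "stop_early"
}

#' Final decision
#'
#' The agent is deemed worthy only if the stage-1 gate passed and the total
#' response count reaches `r`.
#'
#' @param x_total total responses over all enrolled patients.
#' @param d a [two_stage_design()].
#' @param x1 stage-1 responses (needed to confirm the interim gate).
#' @return `"worthy"` or `"not_worthy"`.
#' @export
final_decision <- function(x_total, d, x1) {
  stopifnot(inherits(d, "two_stage_design"))
  x_total <- assert_count(x_total, "x_total")
  x1 <- assert_count(x1, "x1")
  if (x_total > d$n_total) stop("x_total cannot exceed n_total")
  if (x1 > d$n1 || x1 > x_total) stop("invalid stage-1 count")
  if (interim_decision(x1, d) == "continue" && x_total >= d$r) {
    "worthy"
  } else {
    "not_worthy"
  }
}
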