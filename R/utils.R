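#' @keywords internal
"_PACKAGE"

#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Independent random streams (cell placement, spot counts, intensities,
#' cohort draws, ...) are obtained by hashing the master seed together with a
#' short stream label, so that adding a stream never perturbs the draws of an
#' existing one. The hash is a 32-bit multiplicative scheme kept strictly
#' below 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param stream character scalar naming the stream.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# run expr with a local RNG state seeded from (seed, stream)
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}

#' The four immuno-FISH cell populations
#'
#' Cells are classified by pSTAT3 positivity crossed with JAK2 amplification.
#' The order is fixed throughout the package and matches the order of the
#' `fractions` field of [slide_spec()].
#'
#' @return character vector of the four population labels.
#' @export
population_levels <- function() {
  c("pSTAT3-/JAK2noamp", "pSTAT3+/JAK2noamp",
    "pSTAT3-/JAK2amp",  "pSTAT3+/JAK2amp")
}

# population index (1..4) from the two booleans
population_from_calls <- function(pstat3_pos, jak2_amp) {
  idx <- 1L + as.integer(pstat3_pos) + 2L * as.integer(jak2_amp)
  factor(population_levels()[idx], levels = population_levels())
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
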