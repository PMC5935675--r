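# Synthetic-data generators: slides (images + cell tables), trial cohorts,
# and pre/post expression matrices with known ground truth.

#' Specification of a synthetic immuno-FISH slide
#'
#' Describes a mixture of the four tumor-cell populations
#' (pSTAT3 status x JAK2 amplification, order as [population_levels()])
#' rendered on a multi-channel section image. The defaults encode the
#' package's stated world: diploid cells carry ~2 JAK2 and ~2 CEP9 copies,
#' amplified cells ~6 JAK2 copies, and pSTAT3-positive nuclei stain around
#' intensity 160 versus 30 for negative nuclei on an 8-bit scale.
#'
#' @param width,height slide dimensions in pixels (>= 64).
#' @param n_cells number of cells to place (>= 1).
#' @param fractions length-4 vector of population proportions summing to 1,
#'   in the order of [population_levels()].
#' @param clustering nonnegative scalar; 0 means complete spatial randomness,
#'   larger values give tighter parent/offspring (Thomas-process-like)
#'   clusters whose members share a population label.
#' @param nucleus_radius nucleus radius in pixels; centroids are kept at
#'   least one diameter apart so nuclei never touch.
#' @param spot_copies 4x2 matrix of per-population true copy numbers,
#'   columns JAK2 and CEP9. Default: non-amplified 2/2, amplified 6/2, so a
#'   JAK2/CEP9 ratio threshold of 2 separates the populations.
#' @param spot_model `"detection"` (default) draws
#'   `Binomial(copies, p_detect) + Poisson(bg)` spots per probe, emulating
#'   hybridization dropout plus background; `"poisson"` draws
#'   `Poisson(copies)` spots.
#' @param p_detect per-copy detection probability for the detection model.
#' @param spot_bg mean number of spurious background spots per nucleus.
#' @param pstat3_low,pstat3_high,pstat3_sd means and common SD of the
#'   low/high nuclear pSTAT3 intensity Gaussians (8-bit scale).
#' @param noise background intensity SD added to every channel.
#' @param seed integer master seed; all draws derive from it via
#'   [derive_seed()].
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(width = 512L, height = 512L, n_cells = 200L,
                       fractions = c(0.25, 0.25, 0.25, 0.25),
                       clustering = 0,
                       nucleus_radius = 12L,
                       spot_copies = rbind(c(2L, 2L), c(2L, 2L),
                                           c(6L, 2L), c(6L, 2L)),
                       spot_model = c("detection", "poisson"),
                       p_detect = 0.95, spot_bg = 0.05,
                       pstat3_low = 30, pstat3_high = 160, pstat3_sd = 15,
                       noise = 5, seed = 1L) {
  spot_model <- match.arg(spot_model)
  n_cells <- assert_count(n_cells, "n_cells", min = 1L)
  if (width < 64 || height < 64) stop("width and height must be >= 64")
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be 4 nonnegative proportions summing to 1")
  }
  if (clustering < 0) stop("`clustering` must be nonnegative")
  stopifnot(is.matrix(spot_copies), dim(spot_copies) == c(4L, 2L),
            all(spot_copies >= 0))
  assert_prob(p_detect, "p_detect")
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = n_cells, fractions = as.numeric(fractions),
               clustering = clustering,
               nucleus_radius = as.integer(nucleus_radius),
               spot_copies = spot_copies, spot_model = spot_model,
               p_detect = p_detect, spot_bg = spot_bg,
               pstat3_low = pstat3_low, pstat3_high = pstat3_high,
               pstat3_sd = pstat3_sd, noise = noise,
               seed = as.integer(seed))
  class(spec) <- "slide_spec"
  spec
}

# dart-throwing placement with a hard minimum centroid distance, using a
# coarse grid hash so each candidate only checks nearby accepted points
place_points <- function(n, width, height, min_dist, margin,
                         max_tries = 200L * n) {
  if ((width - 2 * margin) < min_dist || (height - 2 * margin) < min_dist) {
    stop("slide too small for the requested nucleus size")
  }
  cell <- min_dist
  nxg <- max(1L, ceiling(width / cell))
  nyg <- max(1L, ceiling(height / cell))
  grid <- vector("list", nxg * nyg)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L; tries <- 0L
  d2 <- min_dist^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "could not place %d non-overlapping nuclei in %dx%d after %d tries",
        n, width, height, max_tries))
    }
    x <- runif(1, margin, width - margin)
    y <- runif(1, margin, height - margin)
    gx <- min(nxg, 1L + floor(x / cell)); gy <- min(nyg, 1L + floor(y / cell))
    ok <- TRUE
    for (ix in max(1L, gx - 1L):min(nxg, gx + 1L)) {
      for (iy in max(1L, gy - 1L):min(nyg, gy + 1L)) {
        idx <- grid[[(iy - 1L) * nxg + ix]]
        if (length(idx) &&
            any((xs[idx] - x)^2 + (ys[idx] - y)^2 < d2)) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      g <- (gy - 1L) * nxg + gx
      grid[[g]] <- c(grid[[g]], placed)
    }
  }
  data.frame(x = xs, y = ys)
}

# draw per-cell population labels and positions; under clustering > 0,
# parent points carry a population and offspring inherit it
draw_cells <- function(spec) {
  n <- spec$n_cells
  # a 5-px guard band beyond one diameter keeps blurred nuclei separable
  min_dist <- 2 * spec$nucleus_radius + 5
  margin <- spec$nucleus_radius + 2
  if (spec$clustering <= 0) {
    pos <- place_points(n, spec$width, spec$height, min_dist, margin)
    pop <- sample.int(4L, n, replace = TRUE, prob = spec$fractions)
    return(cbind(pos, population_idx = pop))
  }
  # Thomas-like: uniform parents, Gaussian offspring displacement with
  # sd shrinking as `clustering` grows; hard-core thinning keeps nuclei apart
  n_parents <- max(2L, ceiling(n / 40))
  sd_off <- min(spec$width, spec$height) / (4 * spec$clustering)
  px <- runif(n_parents, margin, spec$width - margin)
  py <- runif(n_parents, margin, spec$height - margin)
  ppop <- sample.int(4L, n_parents, replace = TRUE, prob = spec$fractions)
  cell <- min_dist
  nxg <- max(1L, ceiling(spec$width / cell))
  nyg <- max(1L, ceiling(spec$height / cell))
  grid <- vector("list", nxg * nyg)
  xs <- numeric(n); ys <- numeric(n); pop <- integer(n)
  placed <- 0L; tries <- 0L; max_tries <- 400L * n
  d2 <- min_dist^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place clustered nuclei without overlap; enlarge slide")
    }
    k <- sample.int(n_parents, 1L)
    x <- rnorm(1, px[k], sd_off); y <- rnorm(1, py[k], sd_off)
    if (x < margin || x > spec$width - margin ||
        y < margin || y > spec$height - margin) next
    gx <- min(nxg, 1L + floor(x / cell)); gy <- min(nyg, 1L + floor(y / cell))
    ok <- TRUE
    for (ix in max(1L, gx - 1L):min(nxg, gx + 1L)) {
      for (iy in max(1L, gy - 1L):min(nyg, gy + 1L)) {
        idx <- grid[[(iy - 1L) * nxg + ix]]
        if (length(idx) && any((xs[idx] - x)^2 + (ys[idx] - y)^2 < d2)) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y; pop[placed] <- ppop[k]
      g <- (gy - 1L) * nxg + gx
      grid[[g]] <- c(grid[[g]], placed)
    }
  }
  data.frame(x = xs, y = ys, population_idx = pop)
}

draw_spots <- function(spec, copies) {
  n <- length(copies)
  if (spec$spot_model == "poisson") {
    rpois(n, copies)
  } else {
    rbinom(n, copies, spec$p_detect) + rpois(n, spec$spot_bg)
  }
}

#' Generate a ground-truth cell table for a synthetic slide
#'
#' The fast path of the generator: the same cell-level draws as
#' [generate_slide_image()] without rendering pixels. Optionally adds
#' CD8/GZMB infiltrate flags whose per-cell rate decreases with the slide's
#' realized Shannon diversity (logistic link), emulating the negative
#' diversity-infiltrate association.
#'
#' @param spec a [slide_spec()].
#' @param include_infiltrate logical; add `cd8`/`gzmb` flags.
#' @param cd8_intercept,cd8_slope logistic-scale intercept and slope of the
#'   per-cell CD8 rate on realized Shannon diversity (nats); the default
#'   slope is negative.
#' @param gzmb_rate probability that a CD8+ cell is GZMB+.
#' @return data.frame with columns cell_id, x, y, jak2_spots, cep9_spots,
#'   pstat3_intensity, pstat3_pos, cd8, gzmb, population.
#' @export
generate_cell_table <- function(spec, include_infiltrate = FALSE,
                                cd8_intercept = -0.5, cd8_slope = -1.5,
                                gzmb_rate = 0.4) {
  stopifnot(inherits(spec, "slide_spec"))
  cells <- with_stream_seed(spec$seed, "cells", draw_cells(spec))
  pop <- cells$population_idx
  n <- nrow(cells)
  spots <- with_stream_seed(spec$seed, "spots", {
    list(jak2 = draw_spots(spec, spec$spot_copies[pop, 1L]),
         cep9 = draw_spots(spec, spec$spot_copies[pop, 2L]))
  })
  pos <- pop %in% c(2L, 4L)
  intensity <- with_stream_seed(spec$seed, "pstat3", {
    mu <- ifelse(pos, spec$pstat3_high, spec$pstat3_low)
    pmin(pmax(rnorm(n, mu, spec$pstat3_sd), 0), 255)
  })
  cd8 <- gzmb <- rep(NA, n)
  if (include_infiltrate) {
    frac <- tabulate(pop, nbins = 4L) / n
    h <- shannon_entropy(frac)
    flags <- with_stream_seed(spec$seed, "infiltrate", {
      p_cd8 <- stats::plogis(cd8_intercept + cd8_slope * h)
      cd8 <- runif(n) < p_cd8
      gzmb <- cd8 & (runif(n) < gzmb_rate)
      list(cd8 = cd8, gzmb = gzmb)
    })
    cd8 <- flags$cd8; gzmb <- flags$gzmb
  }
  data.frame(
    cell_id = seq_len(n),
    x = cells$x, y = cells$y,
    jak2_spots = spots$jak2, cep9_spots = spots$cep9,
    pstat3_intensity = intensity,
    pstat3_pos = pos,
    cd8 = cd8, gzmb = gzmb,
    population = factor(population_levels()[pop],
                        levels = population_levels())
  )
}

# additively paint filled disks of given per-cell values onto a matrix
paint_disks <- function(img, cx, cy, radius, values) {
  h <- nrow(img); w <- ncol(img)
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  for (i in seq_along(cx)) {
    rows <- round(cy[i]) + off$dy + 1L  # y is 0-based row
    cols <- round(cx[i]) + off$dx + 1L
    keep <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
    img[cbind(rows[keep], cols[keep])] <-
      img[cbind(rows[keep], cols[keep])] + values[i]
  }
  img
}

# paint small Gaussian puncta (FISH spots) at the given coordinates
paint_puncta <- function(img, sx, sy, amplitude = 200, sigma = 1.2) {
  if (!length(sx)) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sigma)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  gk <- amplitude * exp(-(off$dx^2 + off$dy^2) / (2 * sigma^2))
  for (i in seq_along(sx)) {
    rows <- round(sy[i]) + off$dy + 1L
    cols <- round(sx[i]) + off$dx + 1L
    keep <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
    img[cbind(rows[keep], cols[keep])] <-
      img[cbind(rows[keep], cols[keep])] + gk[keep]
  }
  img
}

#' Render a synthetic 4-channel immuno-FISH slide image
#'
#' Renders the ground truth of [generate_cell_table()] as pixel data:
#' nuclei as non-touching filled disks on the nuclear (DAPI) channel,
#' per-cell FISH spots as Gaussian puncta placed inside each nucleus on the
#' JAK2 and CEP9 channels, and the pSTAT3 channel as nuclei filled with the
#' cell's drawn intensity. Gaussian background noise is added to every
#' channel. Channel order is DAPI, JAK2, CEP9, pSTAT3 throughout.
#'
#' @param spec a [slide_spec()].
#' @return list with `image` (named list of 4 numeric matrices, rows = y,
#'   columns = x, 0-based pixel coordinates with x = column and y = row) and
#'   `cells` (the ground-truth table).
#' @export
generate_slide_image <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  cells <- generate_cell_table(spec)
  h <- spec$height; w <- spec$width; r <- spec$nucleus_radius
  blank <- function() matrix(10, nrow = h, ncol = w)
  dapi <- paint_disks(blank(), cells$x, cells$y, r, rep(170, nrow(cells)))
  pstat3 <- paint_disks(blank(), cells$x, cells$y, r, cells$pstat3_intensity)
  # place each cell's puncta within 0.75 r of its centroid, at least 5 px
  # apart (distinct chromosome territories) so detected peaks stay resolved
  spot_xy <- function(counts) {
    xs <- numeric(sum(counts)); ys <- numeric(sum(counts)); k <- 0L
    for (i in which(counts > 0L)) {
      got <- 0L; tries <- 0L
      px <- numeric(counts[i]); py <- numeric(counts[i])
      while (got < counts[i]) {
        tries <- tries + 1L
        rad <- sqrt(runif(1)) * (r - 3)
        ang <- runif(1, 0, 2 * pi)
        x <- rad * cos(ang); y <- rad * sin(ang)
        if (got == 0L || tries > 60L ||
            all((px[seq_len(got)] - x)^2 + (py[seq_len(got)] - y)^2 >= 25)) {
          got <- got + 1L
          px[got] <- x; py[got] <- y
        }
      }
      xs[k + seq_len(got)] <- cells$x[i] + px
      ys[k + seq_len(got)] <- cells$y[i] + py
      k <- k + got
    }
    list(x = xs, y = ys)
  }
  jak2 <- with_stream_seed(spec$seed, "render_jak2", {
    p <- spot_xy(cells$jak2_spots)
    paint_puncta(blank(), p$x, p$y)
  })
  cep9 <- with_stream_seed(spec$seed, "render_cep9", {
    p <- spot_xy(cells$cep9_spots)
    paint_puncta(blank(), p$x, p$y)
  })
  img <- with_stream_seed(spec$seed, "noise", {
    lapply(list(dapi = dapi, jak2 = jak2, cep9 = cep9, pstat3 = pstat3),
           function(ch) pmax(ch + matrix(rnorm(h * w, 0, spec$noise), h, w), 0))
  })
  list(image = img, cells = cells)
}

#' Specification of a synthetic single-arm trial cohort
#'
#' @param n_patients number of treated patients.
#' @param response_prob probability of objective response (CR/PR).
#' @param median_pfs,median_os exponential medians in months.
#' @param censor_rate target probability that an observation is censored
#'   (independent exponential censoring; 1 censors everything).
#' @param sd_prob probability a non-responder's best response is SD.
#' @param sd_gt24_prob probability an SD lasts more than 24 weeks.
#' @param ne_prob probability a non-responder is unevaluable (NE).
#' @param ae_profile named list: AE name -> length-4 vector of per-grade
#'   probabilities (grades 1-4; remainder = no event).
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 21L, response_prob = 0.05,
                        median_pfs = 1.2, median_os = 4.5,
                        censor_rate = 0.1,
                        sd_prob = 0.15, sd_gt24_prob = 0.3, ne_prob = 0.05,
                        ae_profile = list(
                          fatigue = c(0.38, 0.19, 0, 0),
                          anemia  = c(0.05, 0.10, 0.14, 0),
                          nausea  = c(0.10, 0.05, 0, 0)),
                        seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients", min = 1L)
  assert_prob(c(response_prob, censor_rate, sd_prob, sd_gt24_prob, ne_prob),
              "probabilities")
  if (median_pfs <= 0 || median_os <= 0) stop("medians must be > 0")
  for (p in ae_profile) {
    if (length(p) != 4L || any(p < 0) || sum(p) > 1) {
      stop("each ae_profile entry must be 4 grade probabilities summing <= 1")
    }
  }
  structure(list(n_patients = n_patients, response_prob = response_prob,
                 median_pfs = median_pfs, median_os = median_os,
                 censor_rate = censor_rate, sd_prob = sd_prob,
                 sd_gt24_prob = sd_gt24_prob, ne_prob = ne_prob,
                 ae_profile = ae_profile, seed = as.integer(seed)),
            class = "cohort_spec")
}

# exponential survival time with given median, independently censored so
# that P(censored) equals censor_rate (competing exponential censoring)
draw_survival <- function(n, median, censor_rate) {
  rate <- log(2) / median
  t <- rexp(n, rate)
  if (censor_rate >= 1) {
    return(data.frame(time = rexp(n, rate), event = rep(0L, n)))
  }
  if (censor_rate <= 0) {
    return(data.frame(time = t, event = rep(1L, n)))
  }
  rate_c <- censor_rate / (1 - censor_rate) * rate
  cns <- rexp(n, rate_c)
  data.frame(time = pmin(t, cns), event = as.integer(t <= cns))
}

#' Generate a synthetic trial cohort
#'
#' Patient-level best responses are Bernoulli responders (PR) with
#' non-responders split among SD, PD and NE; PFS and OS are exponential with
#' the specified medians under independent exponential censoring; adverse
#' events are drawn per patient from the per-grade profile (the recorded
#' grade is the patient's maximum for that event).
#'
#' @param spec a [cohort_spec()].
#' @return object of class `trial_cohort`: list with `patients` (data.frame:
#'   patient_id, best_response, sd_duration_weeks, pfs_months, pfs_event,
#'   os_months, os_event) and `ae` (long data.frame: patient_id, ae_name,
#'   max_grade).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  best <- with_stream_seed(spec$seed, "response", {
    resp <- runif(n) < spec$response_prob
    out <- rep("PD", n)
    out[resp] <- "PR"
    nr <- which(!resp)
    u <- runif(length(nr))
    out[nr[u < spec$ne_prob]] <- "NE"
    out[nr[u >= spec$ne_prob & u < spec$ne_prob + spec$sd_prob]] <- "SD"
    out
  })
  sd_dur <- with_stream_seed(spec$seed, "sd_duration", {
    dur <- rep(NA_real_, n)
    is_sd <- best == "SD"
    long <- runif(n) < spec$sd_gt24_prob
    dur[is_sd] <- ifelse(long[is_sd], 24 + rexp(sum(is_sd), 1 / 10),
                         runif(sum(is_sd), 6, 24))
    dur
  })
  pfs <- with_stream_seed(spec$seed, "pfs",
                          draw_survival(n, spec$median_pfs, spec$censor_rate))
  os <- with_stream_seed(spec$seed, "os",
                         draw_survival(n, spec$median_os, spec$censor_rate))
  ae <- with_stream_seed(spec$seed, "ae", {
    rows <- list()
    for (nm in names(spec$ae_profile)) {
      p <- spec$ae_profile[[nm]]
      g <- apply(rmultinom(n, 1L, c(1 - sum(p), p)), 2L, which.max) - 1L
      hit <- g > 0L
      if (any(hit)) {
        rows[[nm]] <- data.frame(patient_id = which(hit), ae_name = nm,
                                 max_grade = g[hit])
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(patient_id = integer(), ae_name = character(),
                 max_grade = integer())
  })
  rownames(ae) <- NULL
  structure(list(
    patients = data.frame(
      patient_id = seq_len(n), best_response = best,
      sd_duration_weeks = sd_dur,
      pfs_months = pfs$time, pfs_event = pfs$event,
      os_months = os$time, os_event = os$event),
    ae = ae), class = "trial_cohort")
}

#' Specification of a synthetic pre/post expression experiment
#'
#' Negative-binomial counts for `n_genes` genes over baseline and cycle-2
#' samples. Genes in `signature_genes` (STAT3-induced) receive a
#' `target_effect` log2 fold-change post-treatment (negative = repression);
#' genes in `repressed_genes` receive the opposite shift.
#'
#' @param n_genes total genes (>= total signature size).
#' @param n_pre,n_post baseline and cycle-2 sample counts.
#' @param signature_genes list of two character vectors (the two STAT3
#'   signatures); defaults to the bundled synthetic placeholder signatures.
#' @param repressed_genes character vector of STAT3-repressed genes.
#' @param target_effect log2 fold-change applied post-treatment to induced
#'   genes (and negated for repressed genes).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param gene_lengths optional per-gene effective lengths in kb; drawn from
#'   a gamma with mean ~2 kb when NULL.
#' @param seed integer master seed.
#' @return object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 1000L, n_pre = 11L, n_post = 4L,
                            signature_genes = default_signatures(),
                            repressed_genes = c("LCK", "CD3E", "ZAP70"),
                            target_effect = -1, dispersion = 0.2,
                            gene_lengths = NULL, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  if (dispersion <= 0) stop("dispersion must be > 0")
  stopifnot(is.list(signature_genes), length(signature_genes) == 2L)
  n_sig <- length(unique(c(unlist(signature_genes), repressed_genes)))
  if (n_genes < n_sig) stop("n_genes must be >= total signature size")
  structure(list(n_genes = n_genes, n_pre = as.integer(n_pre),
                 n_post = as.integer(n_post),
                 signature_genes = signature_genes,
                 repressed_genes = repressed_genes,
                 target_effect = target_effect, dispersion = dispersion,
                 gene_lengths = gene_lengths, seed = as.integer(seed)),
            class = "expression_spec")
}

#' Bundled synthetic STAT3 signature gene lists
#'
#' Two placeholder STAT3-pathway signatures shipped as a GMT fixture
#' (`inst/extdata/stat3_signatures_synthetic.gmt`). The gene symbols are
#' plausible JAK-STAT pathway members but the lists are synthetic
#' stand-ins, not the published signatures.
#'
#' @return named list of two character vectors.
#' @export
default_signatures <- function() {
  path <- system.file("extdata", "stat3_signatures_synthetic.gmt",
                      package = "ifishtrial")
  if (nzchar(path)) return(read_gmt(path))
  # fallback used before installation (e.g. during load_all of a fresh tree)
  list(STAT3_SIG_A = c("SOCS3", "MYC", "JUNB", "BCL3", "OSMR", "IL6R",
                       "MCL1", "PIM1", "CCND1", "ICAM1"),
       STAT3_SIG_B = c("SOCS3", "EGFR", "STAT3", "BCL6", "FOS", "IER3",
                       "SERPINB3", "MUC1", "CD274", "HIF1A"))
}

#' Generate a synthetic pre/post count matrix
#'
#' @param spec an [expression_spec()].
#' @return list with `counts` (genes x samples integer matrix), `gene_lengths`
#'   (named numeric, kb) and `samples` (sample sheet data.frame: sample_id,
#'   patient_id, timepoint, tumor_fraction).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  sig <- unique(unlist(spec$signature_genes))
  rep_genes <- setdiff(spec$repressed_genes, sig)
  n_other <- spec$n_genes - length(sig) - length(rep_genes)
  genes <- c(sig, rep_genes,
             sprintf("GENE%04d", seq_len(max(0L, n_other))))
  n_s <- spec$n_pre + spec$n_post
  timepoint <- rep(c("baseline", "cycle2"), c(spec$n_pre, spec$n_post))
  base_mu <- with_stream_seed(spec$seed, "basemu",
                              2^runif(length(genes), 3, 9))
  lens <- spec$gene_lengths
  if (is.null(lens)) {
    lens <- with_stream_seed(spec$seed, "lengths",
                             rgamma(length(genes), shape = 4, rate = 2))
  }
  lens <- stats::setNames(pmax(as.numeric(lens), 0.1), genes)
  lfc <- numeric(length(genes))
  lfc[genes %in% sig] <- spec$target_effect
  lfc[genes %in% rep_genes] <- -spec$target_effect
  counts <- with_stream_seed(spec$seed, "counts", {
    libsize <- runif(n_s, 0.7, 1.3)
    mu <- outer(base_mu, libsize)
    post <- timepoint == "cycle2"
    mu[, post] <- mu[, post] * 2^lfc
    matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           nrow = length(genes),
           dimnames = list(genes, sprintf("S%02d", seq_len(n_s))))
  })
  samples <- with_stream_seed(spec$seed, "samples", data.frame(
    sample_id = colnames(counts),
    patient_id = sprintf("P%02d", c(seq_len(spec$n_pre), seq_len(spec$n_post))),
    timepoint = timepoint,
    tumor_fraction = runif(n_s, 0.25, 0.95)))
  list(counts = counts, gene_lengths = lens, samples = samples)
}

#' Generate a set of slides spanning a range of diversities
#'
#' Convenience generator for the diversity-infiltrate regression: each slide
#' draws its population mixture from a Dirichlet whose concentration is
#' interpolated between near-degenerate (low diversity) and uniform (high
#' diversity), then generates its cell table with infiltrate flags, so CD8
#' density and realized Shannon diversity are negatively associated across
#' slides.
#'
#' @param n_slides number of slides.
#' @param n_cells cells per slide.
#' @param timepoint label recycled across slides.
#' @param cd8_intercept,cd8_slope passed to [generate_cell_table()].
#' @param seed integer master seed.
#' @return list with `tables` (list of cell tables) and `samples`
#'   (slide_id, patient_id, timepoint).
#' @export
generate_slide_set <- function(n_slides = 30L, n_cells = 150L,
                               timepoint = "primary",
                               cd8_intercept = -0.5, cd8_slope = -1.5,
                               seed = 1L) {
  tables <- vector("list", n_slides)
  mixes <- with_stream_seed(seed, "mixes", {
    lapply(seq_len(n_slides), function(i) {
      # gamma-normalized Dirichlet draw; alpha ramps from 0.15 to 6
      alpha <- 0.15 + (6 - 0.15) * (i - 1) / max(1L, n_slides - 1L)
      g <- rgamma(4L, shape = alpha)
      if (sum(g) == 0) g <- rep(1, 4)
      g / sum(g)
    })
  })
  for (i in seq_len(n_slides)) {
    sp <- slide_spec(n_cells = n_cells, fractions = mixes[[i]],
                     width = 1024L, height = 1024L,
                     seed = derive_seed(seed, paste0("slide", i)))
    tables[[i]] <- generate_cell_table(sp, include_infiltrate = TRUE,
                                       cd8_intercept = cd8_intercept,
                                       cd8_slope = cd8_slope)
  }
  list(tables = tables,
       samples = data.frame(slide_id = sprintf("SL%02d", seq_len(n_slides)),
                            patient_id = sprintf("P%02d", seq_len(n_slides)),
                            timepoint = timepoint))
}
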