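# Immuno-FISH image analysis: nucleus segmentation, per-nucleus FISH spot
# counting, and per-cell pSTAT3 / JAK2-amplification calling.

#' Segmentation and calling parameters
#'
#' @param nuclear_threshold_method `"otsu"` (per-image) or `"fixed"`.
#' @param nuclear_threshold fixed nuclear threshold (used when method is
#'   `"fixed"`).
#' @param min_nucleus_area,max_nucleus_area area bounds in px^2 applied to
#'   candidate nuclei (defaults bracket a disk of radius 12).
#' @param blur_sigma Gaussian SD applied to the nuclear channel before
#'   thresholding.
#' @param spot_sigma_range length-2 vector, the difference-of-Gaussians
#'   scales (px) bracketing the expected spot size.
#' @param spot_min_prominence minimum DoG response at a spot maximum.
#' @param pstat3_threshold_method `"otsu"` (over per-nucleus means, per
#'   slide) or `"fixed"`.
#' @param pstat3_threshold fixed positivity threshold.
#' @param amp_rule `"ratio"` (JAK2/CEP9 ratio with a floored reference) or
#'   `"absolute"` (JAK2 spot count alone).
#' @param amp_ratio ratio threshold for amplification (conventional FISH
#'   criterion 2).
#' @param cep9_floor minimum value of the CEP9 denominator. Default 2, the
#'   diploid expectation: observing fewer than two reference signals in a
#'   nucleus reflects hybridization dropout rather than monosomy, and
#'   flooring at 1 would let a single dropped CEP9 spot halve the
#'   denominator and miscall diploid cells as amplified. Set to 1 for the
#'   permissive floor.
#' @param amp_min_spots absolute JAK2 spot threshold for `"absolute"`.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(nuclear_threshold_method = c("otsu", "fixed"),
                                nuclear_threshold = 50,
                                min_nucleus_area = 100,
                                max_nucleus_area = 2000,
                                blur_sigma = 1.5,
                                spot_sigma_range = c(1, 2.5),
                                spot_min_prominence = 15,
                                pstat3_threshold_method = c("otsu", "fixed"),
                                pstat3_threshold = 95,
                                amp_rule = c("ratio", "absolute"),
                                amp_ratio = 2, cep9_floor = 2L,
                                amp_min_spots = 4L) {
  stopifnot(min_nucleus_area > 0, max_nucleus_area > min_nucleus_area,
            length(spot_sigma_range) == 2L,
            spot_sigma_range[1] < spot_sigma_range[2])
  structure(list(
    nuclear_threshold_method = match.arg(nuclear_threshold_method),
    nuclear_threshold = nuclear_threshold,
    min_nucleus_area = min_nucleus_area,
    max_nucleus_area = max_nucleus_area,
    blur_sigma = blur_sigma,
    spot_sigma_range = spot_sigma_range,
    spot_min_prominence = spot_min_prominence,
    pstat3_threshold_method = match.arg(pstat3_threshold_method),
    pstat3_threshold = pstat3_threshold,
    amp_rule = match.arg(amp_rule),
    amp_ratio = amp_ratio, cep9_floor = as.integer(cep9_floor),
    amp_min_spots = amp_min_spots),
    class = "segmentation_params")
}

#' Segment nuclei from the nuclear (DAPI) channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), 8-connected
#' component labeling, then an area filter that removes debris below
#' `min_nucleus_area` and clumps above `max_nucleus_area`. A blank image
#' yields zero nuclei, not an error.
#'
#' @param nuclear single-channel numeric matrix.
#' @param params a [segmentation_params()].
#' @return list with `labels` (integer matrix, relabeled 1..K) and
#'   `nuclei` (data.frame: label, area, x, y centroids in 0-based pixels).
#' @export
segment_nuclei <- function(nuclear, params = segmentation_params()) {
  stopifnot(is.matrix(nuclear))
  sm <- gaussian_blur(nuclear, params$blur_sigma)
  thr <- if (params$nuclear_threshold_method == "otsu") {
    if (max(sm) <= min(sm)) Inf else otsu_threshold(sm)
  } else {
    params$nuclear_threshold
  }
  mask <- sm > thr
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(nuclear), ncol(nuclear)),
                nuclei = region_props(matrix(0L, 1, 1))[0, ]))
  }
  lab <- label_components(mask)
  props <- region_props(lab)
  keep <- props$area >= params$min_nucleus_area &
    props$area <= params$max_nucleus_area
  kept <- props$label[keep]
  lab[!(lab %in% kept)] <- 0L
  lab[lab > 0L] <- match(lab[lab > 0L], kept)
  props <- props[keep, , drop = FALSE]
  props$label <- seq_len(nrow(props))
  rownames(props) <- NULL
  list(labels = lab, nuclei = props)
}

#' Count FISH spots per nucleus
#'
#' Spots are local maxima of a band-pass (difference-of-Gaussians over
#' `spot_sigma_range`) response exceeding `spot_min_prominence`; each spot
#' is assigned to the nucleus label under its maximum, and spots outside
#' all nuclei are discarded.
#'
#' @param channel spot-channel matrix (same shape as `labels`).
#' @param labels nucleus label matrix from [segment_nuclei()].
#' @param params a [segmentation_params()].
#' @return integer vector of counts, one per nucleus label 1..K.
#' @export
count_spots <- function(channel, labels, params = segmentation_params()) {
  if (!all(dim(channel) == dim(labels))) {
    stop("channel and label image must have the same shape")
  }
  n_lab <- max(labels, 0L)
  if (n_lab == 0L) return(integer(0))
  dog <- gaussian_blur(channel, params$spot_sigma_range[1]) -
    gaussian_blur(channel, params$spot_sigma_range[2])
  peaks <- local_maxima(dog) & dog > params$spot_min_prominence & labels > 0L
  tabulate(labels[peaks], nbins = n_lab)
}

#' Call per-cell phenotype and copy-number status
#'
#' pSTAT3 positivity: mean nuclear intensity above a per-slide Otsu
#' threshold over the per-nucleus means (or a fixed threshold). JAK2
#' amplification: spot-count ratio JAK2 / max(CEP9, cep9_floor) at or
#' above `amp_ratio` (conventional FISH criterion with a diploid-floored
#' reference), or the absolute rule `jak2_spots >= amp_min_spots`. Cells
#' with zero CEP9 spots are retained under the floor rule and flagged.
#'
#' @param labels nucleus label matrix.
#' @param jak2_spots,cep9_spots per-nucleus counts from [count_spots()].
#' @param pstat3 pSTAT3 channel matrix.
#' @param params a [segmentation_params()].
#' @return CellRecord data.frame: cell_id, x, y, jak2_spots, cep9_spots,
#'   pstat3_intensity, pstat3_pos, jak2_amp, cep9_zero, population.
#' @export
call_cells <- function(labels, jak2_spots, cep9_spots, pstat3,
                       params = segmentation_params()) {
  props <- region_props(labels)
  n <- nrow(props)
  stopifnot(length(jak2_spots) == n, length(cep9_spots) == n)
  if (n == 0L) {
    return(data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                      jak2_spots = integer(), cep9_spots = integer(),
                      pstat3_intensity = numeric(), pstat3_pos = logical(),
                      jak2_amp = logical(), cep9_zero = logical(),
                      population = factor(character(),
                                          levels = population_levels())))
  }
  if (!all(dim(pstat3) == dim(labels))) stop("pstat3 shape mismatch")
  keep <- labels > 0L
  sums <- rowsum(as.numeric(pstat3[keep]), labels[keep])
  cnts <- tabulate(labels[keep], nbins = n)
  means <- rep(NA_real_, n)
  ids <- as.integer(rownames(sums))
  means[ids] <- sums[, 1] / cnts[ids]
  thr <- if (params$pstat3_threshold_method == "otsu") {
    otsu_threshold(means)
  } else {
    params$pstat3_threshold
  }
  pos <- means > thr
  amp <- if (params$amp_rule == "ratio") {
    (jak2_spots / pmax(cep9_spots, params$cep9_floor)) >= params$amp_ratio
  } else {
    jak2_spots >= params$amp_min_spots
  }
  data.frame(cell_id = props$label, x = props$x, y = props$y,
             jak2_spots = as.integer(jak2_spots),
             cep9_spots = as.integer(cep9_spots),
             pstat3_intensity = as.numeric(means),
             pstat3_pos = as.logical(pos),
             jak2_amp = as.logical(amp),
             cep9_zero = cep9_spots == 0L,
             population = population_from_calls(pos, amp))
}

#' Run the full image pipeline on a 4-channel slide
#'
#' @param image named list of matrices with channels `dapi`, `jak2`,
#'   `cep9`, `pstat3` (the order written by [generate_slide_image()]).
#' @param params a [segmentation_params()].
#' @return CellRecord data.frame as from [call_cells()].
#' @export
analyze_slide <- function(image, params = segmentation_params()) {
  need <- c("dapi", "jak2", "cep9", "pstat3")
  if (!all(need %in% names(image))) {
    stop("image must be a named list with channels: ",
         paste(need, collapse = ", "))
  }
  seg <- segment_nuclei(image$dapi, params)
  jk <- count_spots(image$jak2, seg$labels, params)
  cp <- count_spots(image$cep9, seg$labels, params)
  call_cells(seg$labels, jk, cp, image$pstat3, params)
}

#' Write / read a multi-channel slide image as plain text
#'
#' Portable text serialization standing in for multi-page TIFF (no TIFF
#' codec is available in this stack): each channel is a header line
#' `#channel <name> <nrow> <ncol>` followed by one whitespace-separated row
#' of pixel values per line. Channel order: dapi, jak2, cep9, pstat3.
#'
#' @param image named list of numeric matrices.
#' @param path file path.
#' @return `read_slide_image` returns the named list of matrices.
#' @export
write_slide_image <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(image)) {
    ch <- image[[nm]]
    writeLines(sprintf("#channel %s %d %d", nm, nrow(ch), ncol(ch)), con)
    utils::write.table(format(ch, digits = 7, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_slide_image
#' @export
read_slide_image <- function(path) {
  lines <- readLines(path)
  heads <- grep("^#channel ", lines)
  if (!length(heads)) stop("not a slide-image file: ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    parts <- strsplit(lines[heads[i]], " +")[[1]]
    nm <- parts[2]; nr <- as.integer(parts[3]); nc <- as.integer(parts[4])
    block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    vals <- scan(text = block, quiet = TRUE)
    if (length(vals) != nr * nc) stop("corrupt channel block: ", nm)
    out[[nm]] <- matrix(vals, nrow = nr, byrow = TRUE)
  }
  out
}
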