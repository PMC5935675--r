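# Low-level image primitives used by the immuno-FISH pipeline. Images are
# numeric matrices with rows = y and columns = x; pixel coordinates are
# 0-based with x = column and y = row. No image-analysis dependency is
# available offline, so Gaussian filtering, Otsu thresholding, connected
# components and difference-of-Gaussians spot detection are implemented
# here directly.

# replicate-pad a matrix by k pixels on every side
pad_replicate <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  ri <- c(rep(1L, k), seq_len(h), rep(h, k))
  ci <- c(rep(1L, k), seq_len(w), rep(w, k))
  img[ri, ci, drop = FALSE]
}

#' Gaussian blur of an image
#'
#' Separable Gaussian convolution with replicate edge padding.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian SD in pixels.
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  k <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-k:k)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  p <- pad_replicate(img, k)
  h <- nrow(img); w <- ncol(img)
  # horizontal pass (over padded columns), accumulate shifted slices
  out <- matrix(0, nrow(p), w)
  for (i in seq_along(kern)) {
    out <- out + kern[i] * p[, i:(i + w - 1L), drop = FALSE]
  }
  # vertical pass
  res <- matrix(0, h, w)
  for (i in seq_along(kern)) {
    res <- res + kern[i] * out[i:(i + h - 1L), , drop = FALSE]
  }
  res
}

#' Otsu threshold of a set of intensities
#'
#' Classic maximum between-class-variance threshold on a 256-bin histogram
#' spanning the value range.
#'
#' @param values numeric vector or matrix.
#' @param n_bins histogram resolution.
#' @return threshold on the original intensity scale; values strictly above
#'   it are "foreground".
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values for Otsu threshold")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  brk <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), n_bins)
  p <- counts / sum(counts)
  mids <- (brk[-1L] + brk[-length(brk)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation over the 8-neighborhood; labels are
#' relabeled to consecutive integers 1..K in raster order of first pixel.
#'
#' @param mask logical matrix.
#' @return integer label matrix (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  idx <- matrix(seq_len(h * w), h, w)
  lab[mask] <- idx[mask]  # unique provisional labels = linear index
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    new <- lab
    for (s in shifts) {
      dr <- s[1]; dc <- s[2]
      src_r <- max(1, 1 - dr):min(h, h - dr)
      dst_r <- src_r + dr
      src_c <- max(1, 1 - dc):min(w, w - dc)
      dst_c <- src_c + dc
      nb <- lab[src_r, src_c, drop = FALSE]
      cur <- new[dst_r, dst_c, drop = FALSE]
      take <- nb > 0L & cur > 0L & nb < cur
      cur[take] <- nb[take]
      new[dst_r, dst_c] <- cur
    }
    if (identical(new, lab)) break
    lab <- new
  }
  u <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], sort(u))
  lab
}

# per-label pixel counts and centroids (0-based x = col, y = row)
region_props <- function(labels) {
  keep <- labels > 0L
  if (!any(keep)) {
    return(data.frame(label = integer(), area = integer(),
                      x = numeric(), y = numeric()))
  }
  lab <- labels[keep]
  rows <- row(labels)[keep] - 1L
  cols <- col(labels)[keep] - 1L
  area <- tabulate(lab)
  sx <- rowsum(as.numeric(cols), lab)
  sy <- rowsum(as.numeric(rows), lab)
  ids <- as.integer(rownames(sx))
  data.frame(label = ids, area = area[ids],
             x = sx[, 1] / area[ids], y = sy[, 1] / area[ids])
}

# TRUE where a pixel is >= all 8 neighbors (replicate-padded comparison)
local_maxima <- function(img) {
  p <- pad_replicate(img, 1L)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- p[(2 + dr):(1 + dr + h), (2 + dc):(1 + dc + w), drop = FALSE]
    out <- out & (img >= nb)
  }
  out
}
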