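# Block spatial/spectral entropy features: Shannon entropy of the gray-level
# histogram and of the normalized AC power of the 2-D DCT, computed on
# non-overlapping blocks at three scales, percentile-trimmed and pooled by
# mean and skewness.

#' Bicubic downsampling at the fixed pipeline scale factors
#'
#' Output dimensions are `round(dim * factor)` per axis (round half up);
#' shrinking uses an antialiased Keys bicubic kernel.
#'
#' @param x numeric matrix (one image channel).
#' @param factor one of 1, 1/2, 1/3.
#' @return resized matrix.
#' @export
downsampleBicubic <- function(x, factor) {
  allowed <- c(1, 1 / 2, 1 / 3)
  if (!any(abs(factor - allowed) < 1e-12))
    stop("factor must be one of 1, 1/2, 1/3")
  if (factor == 1) return(x)
  resizeTo(x, floor(nrow(x) * factor + 0.5), floor(ncol(x) * factor + 0.5))
}

#' Spatial entropy of an image block
#'
#' Shannon entropy (bits) of the 256-level gray histogram; real-valued
#' pixels are rounded to the nearest integer level first.
#'
#' @param block numeric matrix with values in \[0, 255\].
#' @return entropy in \[0, 8\] bits.
#' @export
spatialEntropy <- function(block) {
  if (min(block) < -0.5 || max(block) > 255.5)
    stop("block values must lie in [0, 255]")
  lev <- pmin(pmax(as.integer(round(block)), 0L), 255L)
  p <- tabulate(lev + 1L, 256L) / length(lev)
  shannonEntropyBits(p)
}

#' Spectral entropy of an image block
#'
#' Shannon entropy (bits) of the DC-excluded, power-normalized 2-D
#' orthonormal type-II DCT spectrum. A block with zero AC power returns 0.
#'
#' @param block numeric matrix.
#' @return entropy in \[0, log2(M^2 - 1)\] bits.
#' @export
spectralEntropy <- function(block) {
  Dr <- dctMatrix(nrow(block))
  Dc <- dctMatrix(ncol(block))
  C <- Dr %*% block %*% t(Dc)
  pw <- C^2
  full <- sum(pw)
  pw[1, 1] <- 0
  tot <- sum(pw)
  # all-DC blocks: AC power at floating-point noise level counts as zero
  if (tot <= 1e-20 * max(full, 1)) return(0)
  shannonEntropyBits(as.vector(pw) / tot)
}

# Entropies of all complete M x M blocks tiled from the top-left corner.
blockEntropies <- function(x, M) {
  nbr <- nrow(x) %/% M
  nbc <- ncol(x) %/% M
  if (nbr < 1 || nbc < 1) stop("image too small for one block")
  spac <- spec <- numeric(nbr * nbc)
  k <- 0
  for (bj in seq_len(nbc)) {
    for (bi in seq_len(nbr)) {
      k <- k + 1
      blk <- x[(bi - 1) * M + seq_len(M), (bj - 1) * M + seq_len(M)]
      spac[k] <- spatialEntropy(blk)
      spec[k] <- spectralEntropy(blk)
    }
  }
  list(spatial = spac, spectral = spec)
}

# Keep values within the inclusive [P15, P85] percentile band (linear
# interpolation percentiles), then pool by mean and skewness.
trimPool <- function(v, lower = 0.15, upper = 0.85) {
  q <- quantile(v, c(lower, upper), type = 7, names = FALSE)
  kept <- v[v >= q[1] & v <= q[2]]
  c(mean = mean(kept), skew = skewnessG1(kept))
}

#' Spatial/spectral entropy quality features
#'
#' Computes the 12 pooled entropy features of the green channel: mean and
#' skewness of percentile-trimmed block spatial and spectral entropies at
#' scale factors 1, 1/2 and 1/3 (bicubic, block size `M` at every scale,
#' partial edge blocks discarded).
#'
#' @param imgGreen numeric matrix: green channel of a preprocessed image
#'   (0-255 scale), at least 96 x 96 so the coarsest scale holds one block.
#' @param M block size in pixels.
#' @return named numeric vector of 12 features
#'   (`sseq_{spacen,specen}_{mean,skew}_s{1,2,3}`).
#' @export
sseqFeatures <- function(imgGreen, M = 32) {
  if (min(dim(imgGreen)) < 3 * M)
    stop("image too small for one block at the coarsest scale")
  factors <- c(1, 1 / 2, 1 / 3)
  out <- numeric(0)
  for (si in seq_along(factors)) {
    xs <- downsampleBicubic(imgGreen, factors[si])
    # extension keeps values in range; resampling may overshoot marginally
    xs <- pmin(pmax(xs, 0), 255)
    be <- blockEntropies(xs, M)
    spac <- trimPool(be$spatial)
    spec <- trimPool(be$spectral)
    v <- c(spac["mean"], spac["skew"], spec["mean"], spec["skew"])
    names(v) <- paste0("sseq_", c("spacen_mean", "spacen_skew",
                                  "specen_mean", "specen_skew"),
                       "_s", si)
    out <- c(out, v)
  }
  out
}
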