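# Illumination features from the HSV value channel: median denoising, a
# large Gaussian background estimate that suppresses vessels and small dark
# lesions, and dark-percentile statistics over the FOV.

#' HSV value channel of a preprocessed image
#'
#' V(x, y) = max(R, G, B) / 255, the standard HSV value definition.
#'
#' @param img a [PreprocessedImage-class] or H x W x 3 array (0-255).
#' @return numeric matrix with values in \[0, 1\].
#' @export
valueChannel <- function(img) {
  px <- if (is(img, "PreprocessedImage")) imagePixels(img) else img
  pmin(pmax(pmax(px[, , 1], px[, , 2], px[, , 3]) / 255, 0), 1)
}

#' 5 x 5 median filter of the value channel
#'
#' Exact per-pixel median over the square neighborhood, reflect padding at
#' the edges.
#'
#' @param v numeric matrix, at least 5 x 5.
#' @return filtered matrix.
#' @export
medianFilterV <- function(v) {
  if (min(dim(v)) < 5) stop("grid must be at least 5 x 5")
  median_filter5_cpp(v)
}

#' Gaussian background estimate of the value channel
#'
#' Convolution with a normalized Gaussian of standard deviation `sigma`
#' truncated at +-floor(4 sigma) (153 x 153 support at the default),
#' reflect padding. The wide kernel attenuates vessels and small dark
#' lesions, leaving the illumination field.
#'
#' @param vMed median-filtered value channel.
#' @param sigma Gaussian standard deviation in pixels.
#' @return background matrix in \[0, 1\].
#' @export
gaussianBackground <- function(vMed, sigma = 19) {
  hw <- floor(4 * sigma)
  if (min(dim(vMed)) < 2 * hw + 1)
    stop("grid smaller than the Gaussian kernel")
  k <- gaussianKernel2d(sigma, hw)
  bg <- conv2FFT(vMed, k, "reflect", tag = sprintf("gaussbg%g", sigma))[[1]]
  pmin(pmax(bg, 0), 1)
}

#' Dark-percentile luminosity features
#'
#' Percentiles 1, 5, 10, 15 and 20% of the background luminosity over the
#' FOV pixels (linear-interpolation percentiles) plus the four consecutive
#' differences.
#'
#' @param bg background matrix from [gaussianBackground()].
#' @param fov a [FovMask-class].
#' @return named numeric vector of 9 features (`lum_p*`, `lum_d*`).
#' @export
luminosityFeatures <- function(bg, fov) {
  v <- bg[fovInside(fov)]
  if (length(v) == 0) stop("FOV is empty")
  p <- quantile(v, c(0.01, 0.05, 0.10, 0.15, 0.20), type = 7, names = FALSE)
  out <- c(p, diff(p))
  names(out) <- c("lum_p1", "lum_p5", "lum_p10", "lum_p15", "lum_p20",
                  "lum_d5_1", "lum_d10_5", "lum_d15_10", "lum_d20_15")
  out
}

# Convenience wrapper: all 9 luminosity features of a preprocessed image.
luminosityFromImage <- function(img, sigma = 19) {
  v <- valueChannel(img)
  luminosityFeatures(gaussianBackground(medianFilterV(v), sigma), img@fov)
}
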